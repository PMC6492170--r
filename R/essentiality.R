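# In-silico single-gene deletions and essentiality evaluation.

#' Delete a gene in silico
#'
#' Every reaction whose GPR evaluates to `FALSE` with the gene switched off
#' has its bounds closed to (0, 0).  Isoenzymes (`or`) keep their reactions
#' alive; complexes (`and`) die with any subunit.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id; must be in `model$genes`.
#' @return the constrained model.
#' @export
delete_gene <- function(model, gene) {
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  for (j in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gpr[j]
    if (!nzchar(trimws(g))) next
    if (!gpr_eval(g, off = gene)) {
      model$reactions$lb[j] <- 0
      model$reactions$ub[j] <- 0
    }
  }
  model
}

#' Confusion matrix of essentiality calls
#'
#' The positive class is "experimentally viable predicted viable", so TP is
#' the (majority) class of correctly predicted viable genes.
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP:", x$TP, " TN:", x$TN,
      " FP:", x$FP, " FN:", x$FN, "\n")
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Predictive-power metrics of a confusion matrix
#'
#' PPV, NPV, sensitivity, specificity and predictive success, each as a
#' percentage rounded to the nearest integer (half-up).  A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.  The
#' unrounded percentages are attached as the `"raw"` attribute.
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector of integer percentages.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- c(ppv = safe(cm$TP, cm$TP + cm$FP),
           npv = safe(cm$TN, cm$TN + cm$FN),
           sensitivity = safe(cm$TP, cm$TP + cm$FN),
           specificity = safe(cm$TN, cm$TN + cm$FP),
           predictive_success = safe(cm$TP + cm$TN,
                                     cm$TP + cm$TN + cm$FP + cm$FN))
  out <- round_half_up(raw)
  attr(out, "raw") <- raw
  out
}

#' Evaluate gene essentiality predictions against a reference
#'
#' Runs one deletion FBA per gene in the reference, computes the growth
#' ratio against the wild-type optimum, calls a gene inviable when the ratio
#' falls below `threshold`, and tabulates the confusion matrix against the
#' observed labels (genes with `"unknown"` observation are excluded from the
#' matrix but kept in the calls table).
#'
#' @param model a validated `metabolic_model`.
#' @param reference named character vector: gene -> `"viable"`, `"inviable"`
#'   or `"unknown"`.  Genes absent from the model are skipped with a warning.
#' @param threshold viability threshold on the growth ratio, in (0, 1);
#'   default 0.01.
#' @param tol solver tolerance.
#' @return list with `calls` (data.frame: gene, predicted, observed,
#'   growth_ratio) and `confusion` (a `confusion_matrix`).
#' @export
evaluate_essentiality <- function(model, reference, threshold = 0.01,
                                  tol = 1e-9) {
  stopifnot(threshold > 0, threshold < 1)
  wt <- optimize_growth(model, selection_rule = "solver_default", tol = tol)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("wild-type model does not grow; essentiality is undefined")
  genes <- names(reference)
  absent <- setdiff(genes, model$genes)
  if (length(absent)) {
    warning("genes absent from model skipped: ", paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  ratio <- numeric(length(genes))
  for (k in seq_along(genes)) {
    del <- delete_gene(model, genes[k])
    sol <- optimize_growth(del, selection_rule = "solver_default", tol = tol)
    g <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    ratio[k] <- g / wt$objective_value
  }
  predicted <- ifelse(ratio < threshold, "inviable", "viable")
  observed <- unname(reference[genes])
  calls <- data.frame(gene = genes, predicted = predicted, observed = observed,
                      growth_ratio = ratio, stringsAsFactors = FALSE)
  known <- calls[calls$observed != "unknown", ]
  cm <- confusion_matrix(
    TP = sum(known$observed == "viable" & known$predicted == "viable"),
    TN = sum(known$observed == "inviable" & known$predicted == "inviable"),
    FP = sum(known$observed == "inviable" & known$predicted == "viable"),
    FN = sum(known$observed == "viable" & known$predicted == "inviable"))
  list(calls = calls, confusion = cm)
}

#' Read a reference essentiality list from TSV (`gene  essential{yes,no}`)
#'
#' @param path TSV path.
#' @return named character vector of observed labels (`"inviable"` for
#'   essential genes, `"viable"` otherwise).
#' @export
read_essentiality_reference <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "essential") %in% names(df)))
    stop("reference must have columns: gene, essential")
  stats::setNames(ifelse(tolower(df$essential) %in% c("yes", "true", "1"),
                         "inviable", "viable"), df$gene)
}
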