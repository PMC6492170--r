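<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy_l2" name="toy COBRA-style Level 2 model">
    <listOfCompartments>
      <compartment id="e" name="extracellular"/>
      <compartment id="c" name="cytoplasm"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" name="A (extracellular)" compartment="e"/>
      <species id="A_c" name="A (cytoplasm)" compartment="c"/>
      <species id="B_c" name="B (cytoplasm)" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" name="A exchange" reversible="true">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>EXCHANGE_REACTION: true</p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="1000" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="T_A" name="A transport" reversible="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (g1 and g2) or g3</p>
          <p>MEMBRANE_SPANNING: true</p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R1" name="A to B" reversible="false">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="BIO" name="biomass" reversible="false">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
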