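<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="l3_piecewise">
    <listOfCompartments>
      <compartment id="c" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="X" compartment="c" initialConcentration="1"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k_on" value="2" constant="true"/>
      <parameter id="k_off" value="0.1" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="switching" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <piecewise>
              <piece>
                <apply><times/><ci> k_on </ci><ci> X </ci></apply>
                <apply><lt/>
                  <csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time"> t </csymbol>
                  <cn type="integer"> 5 </cn>
                </apply>
              </piece>
              <otherwise>
                <apply><times/><ci> k_off </ci><ci> X </ci></apply>
              </otherwise>
            </piecewise>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
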