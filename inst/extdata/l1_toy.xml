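<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level1" level="1" version="2">
  <model name="l1_toy">
    <listOfCompartments>
      <compartment name="cell" volume="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species name="A" compartment="cell" initialAmount="1"/>
      <species name="B" compartment="cell" initialAmount="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter name="k1" value="0.5"/>
    </listOfParameters>
    <listOfReactions>
      <reaction name="r1" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="2"/>
          <speciesReference species="A"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B"/>
        </listOfProducts>
        <kineticLaw formula="cell*k1*A"/>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
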