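<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="l2_fundef">
    <listOfFunctionDefinitions>
      <functionDefinition id="mmrate">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <lambda>
            <bvar><ci> x </ci></bvar>
            <bvar><ci> vm </ci></bvar>
            <bvar><ci> km </ci></bvar>
            <apply><divide/>
              <apply><times/><ci> vm </ci><ci> x </ci></apply>
              <apply><plus/><ci> km </ci><ci> x </ci></apply>
            </apply>
          </lambda>
        </math>
      </functionDefinition>
    </listOfFunctionDefinitions>
    <listOfCompartments>
      <compartment id="cyt" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cyt" initialConcentration="1"/>
      <species id="P" compartment="cyt" initialConcentration="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="Vmax" value="1"/>
      <parameter id="Km" value="0.015"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="conv" reversible="false">
        <listOfReactants>
          <speciesReference species="S"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/>
              <cn type="e-notation"> 1.5 <sep/> 0 </cn>
              <apply><ci> mmrate </ci><ci> S </ci><ci> Vmax </ci><ci> Km </ci></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="decay" reversible="false">
        <listOfReactants>
          <speciesReference species="P"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
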