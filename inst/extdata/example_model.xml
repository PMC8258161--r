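<?xml version="1.0" encoding="UTF-8"?>
<!-- Annotated example of the FluxML-subset dialect read by parse_model().

     A two-substrate toy network: substrate SA (3 carbons) is cleaved via two
     routes into a 1-carbon and a 2-carbon pool; the 2-carbon pool condenses
     with substrate SB.  One cleavage is bidirectional, so the model has an
     exchange-flux coordinate. -->
<fluxml name="example">
  <reactionnetwork>
    <metabolitepools>
      <!-- type: "input" = substrate with fixed isotopomer composition,
           "balanced" = intracellular pool with a steady-state balance row,
           "output" = drain (labeling simulated, no balance row).
           atoms = number of carbon atoms. -->
      <pool id="SA" atoms="3" type="input"/>
      <pool id="SB" atoms="2" type="input"/>
      <pool id="A"  atoms="3" type="balanced"/>
      <pool id="B"  atoms="2" type="balanced"/>
      <pool id="C"  atoms="1" type="balanced"/>
      <pool id="D"  atoms="2" type="balanced"/>
      <pool id="E"  atoms="4" type="balanced"/>
      <pool id="Eo" atoms="4" type="output"/>
      <pool id="Do" atoms="2" type="output"/>
      <pool id="Co" atoms="1" type="output"/>
    </metabolitepools>

    <!-- cx: one letter per carbon (position 1 first).  Every educt carbon
         gets a distinct letter; product letters state where each carbon
         ends up (a bijection = carbon conservation). -->
    <reaction id="upt_a">
      <reduct id="SA" cx="abc"/><rproduct id="A" cx="abc"/>
    </reaction>
    <reaction id="upt_b">
      <reduct id="SB" cx="ab"/><rproduct id="B" cx="ab"/>
    </reaction>
    <!-- cleavage: carbon 1 of A becomes C, carbons 2-3 become D -->
    <reaction id="cleave" bidirectional="true">
      <reduct id="A" cx="abc"/>
      <rproduct id="C" cx="a"/><rproduct id="D" cx="bc"/>
    </reaction>
    <!-- condensation: D and B fuse into the 4-carbon product E -->
    <reaction id="cond">
      <reduct id="D" cx="ab"/><reduct id="B" cx="cd"/>
      <rproduct id="E" cx="abcd"/>
    </reaction>
    <reaction id="out_e"><reduct id="E" cx="abcd"/><rproduct id="Eo" cx="abcd"/></reaction>
    <reaction id="out_d"><reduct id="D" cx="ab"/><rproduct id="Do" cx="ab"/></reaction>
    <reaction id="out_c"><reduct id="C" cx="a"/><rproduct id="Co" cx="a"/></reaction>
  </reactionnetwork>

  <constraints>
    <net>
      <!-- net-flux bounds; omitted reactions default to [-100, 100] -->
      <bound flux="upt_b" lo="0" hi="100"/>
      <bound flux="cleave" lo="0" hi="100"/>
      <bound flux="out_d" lo="0" hi="100"/>
      <!-- general linear inequality: upt_b <= 50 (coef * flux <= rhs) -->
      <linear rhs="50" op="le"><coef flux="upt_b" value="1"/></linear>
    </net>
    <xch>
      <!-- exchange bounds for bidirectional reactions (default [0, 200]) -->
      <bound flux="cleave" lo="0" hi="50"/>
    </xch>
  </constraints>

  <measurement>
    <!-- GC-MS mass isotopomer groups: carbon positions of the measured
         fragment and the observed mass shifts (m+0 ... m+k) -->
    <group id="frag_E" metabolite="E" positions="1 2 3 4" shifts="0 1 2 3 4"/>
    <group id="frag_D" metabolite="D" positions="1 2" shifts="0 1 2"/>
    <!-- affine error model: sigma(y) = slope * y + intercept -->
    <errormodel slope="4.120e-2" intercept="6.655e-3"/>
    <!-- extracellular rate measurement with its standard deviation -->
    <rate flux="upt_b" value="40" stddev="2"/>
    <!-- the uptake all fluxes are scaled to (an equality constraint) -->
    <normalization flux="upt_a" value="100"/>
  </measurement>
</fluxml>
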