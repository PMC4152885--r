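<?xml version="1.0" encoding="UTF-8"?>
<!-- 64x64 dynamic vision sensor ("silicon retina"): a pure AER event
     source whose pixels emit events on temporal contrast changes. No
     synapse blocks: the sensor consumes no events. The contrast
     threshold parameter governs the virtual sensor model. -->
<chip id="retina">
  <addressSpecification direction="source" width="12">
    <field name="x" bits="0,1,2,3,4,5" range="63"/>
    <field name="y" bits="6,7,8,9,10,11" range="63"/>
  </addressSpecification>
  <soma label="pixels">
    <dim name="x" offset="0" extent="64"/>
    <dim name="y" offset="0" extent="64"/>
  </soma>
  <parameters>
    <parameter name="contrast threshold" units="log-intensity" value="0.1" key="c_thr"/>
  </parameters>
</chip>
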