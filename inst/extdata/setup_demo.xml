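<?xml version="1.0" encoding="UTF-8"?>
<!-- Two-channel demo board: the sWTA multi-neuron chip on channel 0 and
     the silicon retina on channel 1, driven by the virtual backend. -->
<setup name="demo" channelOffset="16">
  <chip id="ifslwta" channel="0" file="ifslwta.nhml"/>
  <chip id="retina" channel="1" file="retina.nhml"/>
  <api communicator="virtual" configurator="virtual" mapper="virtual"/>
</setup>
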