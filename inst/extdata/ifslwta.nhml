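<?xml version="1.0" encoding="UTF-8"?>
<!-- Multi-neuron soft winner-take-all transceiver chip: a linear array of
     124 excitatory and 4 inhibitory integrate-and-fire neurons with
     hard-wired 1st/2nd/3rd nearest-neighbour excitation and global
     inhibition. Each neuron exposes one excitatory and one inhibitory
     AER synapse (destination addresses); somas emit source events.
     Dynamics parameters are the virtual backend's idealised LIF /
     exponential-current-synapse stand-in for the silicon circuits. -->
<chip id="ifslwta">
  <addressSpecification direction="source" width="7">
    <field name="neuron" bits="0,1,2,3,4,5,6" range="127"/>
  </addressSpecification>
  <addressSpecification direction="destination" width="8">
    <field name="neuron" bits="0,1,2,3,4,5,6" range="127"/>
    <field name="synapse" bits="7" range="1"/>
  </addressSpecification>
  <soma label="excitatory">
    <dim name="neuron" offset="0" extent="124"/>
  </soma>
  <soma label="inhibitory">
    <dim name="neuron" offset="124" extent="4"/>
  </soma>
  <synapse label="excitatory">
    <dim name="neuron" offset="0" extent="128"/>
    <dim name="synapse" offset="0" extent="1"/>
  </synapse>
  <synapse label="inhibitory">
    <dim name="neuron" offset="0" extent="128"/>
    <dim name="synapse" offset="1" extent="1"/>
  </synapse>
  <parameters>
    <parameter name="membrane time constant" units="s" value="0.02" key="tau_m"/>
    <parameter name="input resistance" units="ohm" value="1" key="r_in"/>
    <parameter name="firing threshold" units="V" value="1" key="theta"/>
    <parameter name="reset potential" units="V" value="0" key="v_reset"/>
    <parameter name="refractory period" units="s" value="0.002" key="t_ref"/>
    <parameter name="excitatory synapse time constant" units="s" value="0.005" key="tau_s_exc"/>
    <parameter name="inhibitory synapse time constant" units="s" value="0.005" key="tau_s_inh"/>
    <parameter name="excitatory synapse weight" units="A" value="0.5" key="w_exc"/>
    <parameter name="inhibitory synapse weight" units="A" value="-0.5" key="w_inh"/>
    <parameter name="lateral excitatory weight" units="A" value="0.12" key="w_ee"/>
    <parameter name="excitatory-to-inhibitory weight" units="A" value="0.15" key="w_ei"/>
    <parameter name="inhibitory-to-excitatory weight" units="A" value="-0.4" key="w_ie"/>
    <parameter name="constant bias current" units="A" value="0" key="i_const"/>
    <parameter name="current noise s.d." units="A" value="0" key="noise_sd"/>
  </parameters>
</chip>
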