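cheap_sensors:
  intervention.costs.single: 50.0
high_service_cost:
  intervention.costs.periodic: 40.0
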