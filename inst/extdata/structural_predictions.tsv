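paralog	interactor	region	reference
SYDE1	RhoB	RhoGAP	SwarmDock
SYDE1	RhoA	RhoGAP	SwarmDock
SYDE2	RhoA	RhoGAP	SwarmDock
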