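interactor	category	molecule_class
ATG8 (GABARAP)	intracellular homeostasis	degradation machinery
Ruk/CIN85	synaptogenesis	adaptor
YWHAZ	neuronal differentiation	adaptor
Cyclin B/CDK1	neuronal differentiation	kinase
p38 alpha/beta	intracellular homeostasis	kinase
Casein kinase I gamma	synaptogenesis	kinase
Casein kinase II	synaptogenesis	kinase
Pin1	synaptogenesis	other
Smek1	neuronal differentiation	phosphatase
Grb2	neuronal differentiation	adaptor
Fbw7	neuronal differentiation	degradation machinery
Calcineurin	synaptogenesis	phosphatase
Crk	neuronal differentiation	adaptor
GSK3	synaptogenesis	kinase
RhoA	Rho-family modulator	GTPase
RhoB	Rho-family modulator	GTPase
Munc18	synaptogenesis	other
Liprin-alpha2	synaptogenesis	adaptor
XPO1	intracellular homeostasis	other
ARHGAP28	Rho-family modulator	other
PLEKHG3	Rho-family modulator	other
Mtl	Rho-family modulator	GTPase
Rac1, Rac2	Rho-family modulator	GTPase
RhoA, RhoL	Rho-family modulator	GTPase
Cdc42	Rho-family modulator	GTPase
Neurexin-1	synaptogenesis	other
Bruchpilot	synaptogenesis	other
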