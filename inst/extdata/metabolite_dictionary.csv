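analyte_id,formula,tracer_element,n_traceable
palmitate,C17H34O2,C,16
palmitate_g0,C17H34O2,C,16
palmitate_d2o,C17H34O2,H,22
alanine,C14H32NO2Si2,C,3
aspartate,C18H40NO4Si3,C,4
aspartate_biomass,C18H40NO4Si3,C,4
serine,C17H40NO3Si3,C,3
glyc3p,C3H9O6P,C,3
Glyc3P,C3H9O6P,C,3
acyl16,C16H32O2,C,16
DHCer,C34H69NO3,C,34
Cer,C34H67NO3,C,34
LacCer,C46H87NO13,C,46
GM3,C57H104N2O21,C,57
Gb4,C60H112N2O23,C,60
GM3_boundary,C57H104N2O21,C,57
LPC16,C24H50NO7P,C,24
LPC24,C32H66NO7P,C,32
SM34,C39H79N2O6P,C,39
SM42,C47H95N2O6P,C,47
SM34_boundary,C39H79N2O6P,C,39
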