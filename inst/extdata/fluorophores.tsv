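# Editable dye constants (vendor-style defaults for an Alexa-488-like
# donor and an Alexa-555-like acceptor). Columns match fluorophore_params().
name	ex_max_nm	em_max_nm	extinction_at_max	quantum_yield	a280_correction	abs_fwhm_nm	abs_asymmetry
alexa488	494	520	71000	0.92	0.11	60	-0.10
alexa555	555	570	150000	0.10	0.08	60	-0.15
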