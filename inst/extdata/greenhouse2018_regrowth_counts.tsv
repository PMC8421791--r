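scoring	rg	nrg
first_regrowth_april	203	293
second_regrowth_august	104	392
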