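population	month	rg	nrg
P39	january	83	113
P39	february	66	130
P39	march	61	135
P39	may	50	146
Hp301	january	35	384
Hp301	february	43	376
Hp301	march	33	386
Hp301	may	27	392
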