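metabolite,coefficient,accession,environment
starch,2.58,reference,E1
sucrose,1,reference,E1
no3,0.5,reference,E1
starch,2.4,reference,E2
sucrose,1.05,reference,E2
no3,0.35,reference,E2
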