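code,name,metabolite_id
ala,L-alanine,ala__L_c
arg,L-arginine,arg__L_c
asn,L-asparagine,asn__L_c
asp,L-aspartate,asp__L_c
cys,L-cysteine,cys__L_c
gln,L-glutamine,gln__L_c
glu,L-glutamate,glu__L_c
gly,glycine,gly_c
his,L-histidine,his__L_c
ile,L-isoleucine,ile__L_c
leu,L-leucine,leu__L_c
lys,L-lysine,lys__L_c
met,L-methionine,met__L_c
phe,L-phenylalanine,phe__L_c
pro,L-proline,pro__L_c
ser,L-serine,ser__L_c
thr,L-threonine,thr__L_c
trp,L-tryptophan,trp__L_c
tyr,L-tyrosine,tyr__L_c
val,L-valine,val__L_c
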