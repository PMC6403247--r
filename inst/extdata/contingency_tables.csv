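stage,parameter,a,b,c,d
Campanian,sediment_flux,206,15,7,3
Maastrichtian,sediment_flux,0,3,24,19
total,sediment_flux,206,18,31,22
Campanian,surface_runoff,15,14,125,0
Maastrichtian,surface_runoff,0,6,84,3
total,surface_runoff,15,20,209,3
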