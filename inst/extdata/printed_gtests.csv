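analysis,G,n_pixels,df,adj_order,adj_distance,p_extreme
glc2000,113.347,11.540,4,51.556,33.366,0.044
globcover,663.361,101.140,4,119.991,65.961,0.16
sarvision,2674.893,125.085,4,439.078,239.168,0.00027
population,193.097,11.655,4,87.494,56.561,0.0023
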