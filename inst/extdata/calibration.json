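{"factor":0.817114311933797,"settings":{"lp_sigma":2,"window_radius":3,"region_diameter_px":12,"k_lowest":5},"measured_on":{"sigma":10,"shape":[256,256],"n_seeds":10,"base_seed":555},"per_seed":[0.818008281604668,0.79451128526155,0.816118672289035,0.833068752817524,0.819958364347472,0.816719084864378,0.822856527323997,0.835995877885201,0.795245893574854,0.818660379369286]}
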