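{"simulation":{"species":{"tree":"(((F:0.004,C:0.004):0.003,B:0.007):0.003,A:0.01);","theta":{"F":0.002,"C":0.002,"B":0.002,"A":0.002},"n_individuals":{"F":2,"C":2,"B":2,"A":2}},"contig_lengths":{"chr1":1950000},"base_comp":[0.3,0.2,0.2,0.3],"p_ils":0.1,"block_length":10000,"missing_rate":0.02,"missing_run_length":150,"depth_mean":20,"gq_mean":60,"gq_sd":15,"seed":1},"inputs":null,"L":5000,"G":5000,"min_pi":5,"max_missing_aln":0.1,"gc_range":[0.3,0.7],"min_depth":6,"min_gq":18,"min_mac":1,"window_bp":50000,"step_variants":5,"r2_max":0.5,"q":0.95,"tree_mode":"greedy","focal":"F_1","seed":1,"outdir":null}
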