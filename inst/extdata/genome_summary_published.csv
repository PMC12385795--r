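species,n_genes,n_chromosomes,n_contigs,genome_mb
B. nigra,54886,8,409,515
S. arvensis,48466,9,780,450
S. alba,41132,12,468,436
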