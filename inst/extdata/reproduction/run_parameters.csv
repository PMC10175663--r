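dataset,n_peptides,linkage,n_clusters,components,epsilon,probe_radius,mesh_density,downsample_resolution,patch_max_edges,notes
dataset1,180,ward,2,blosum62+hlathena+hamming+structural,2,1.5,3.0,1.0,16,61 cross-reactive + 119 decoys on HLA-A*01; flat 2-clustering
dataset2,28,ward,NA,blosum62+hlathena+hamming+structural,2,1.5,3.0,1.0,16,HCV response levels; dendrogram mode (no flat cut)
dataset3,73,average,2,blosum62+hlathena+hamming+structural,2,1.5,3.0,1.0,16,28 HCV + 45 viral decoys; flat 2-clustering
dataset4,8,ward,NA,blosum62+hlathena+hamming+structural,2,1.5,3.0,1.0,16,dengue set; dendrogram mode
dataset5,11,ward,NA,blosum62+hlathena+hamming+structural,2,1.5,3.0,1.0,16,HEV-1527 / MYH9-478 pair + 9 decoys; dendrogram + target ranking
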