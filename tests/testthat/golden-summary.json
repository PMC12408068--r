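{
  "seed": 11,
  "thresholds": {
    "loop_fdr_max": 0.01,
    "loop_min_pets": 5,
    "diff_fdr_max": 0.01,
    "diff_min_total_pets": 8,
    "diff_strong_pets": 5,
    "cpm_pseudocount": 0.5,
    "speckle_percentile": 0.9,
    "pileup_W": 10,
    "pileup_blacklist_dist": 1000,
    "de_p_adj_max": 0.05,
    "de_lfc_min": 0.5,
    "kmeans_K": 4
  },
  "simulate": {
    "n_peaks": 202,
    "n_loops": 163,
    "n_genes": 80,
    "n_hubs": 12,
    "n_specific_truth": 40
  },
  "peaks": {
    "n_condition_specific": 40,
    "category_proportions": {
      "group": ["all", "specific"],
      "n": [162, 40],
      "promoter": [0, 0],
      "TTS": [0.01234568, 0],
      "exon": [0.09876543, 0.5],
      "intron": [0.08641975, 0.375],
      "intergenic": [0.80246914, 0.125]
    }
  },
  "topology": {
    "n_loops_filtered": 133,
    "fraction_specific_looping": 0.475,
    "fraction_all_looping": 0.56930693,
    "cutoff_count": 2,
    "n_highly_looping": 24
  },
  "diffloops": {
    "n_kept": 133,
    "group_log2fc": {
      "group": ["other", "specific_anchor"],
      "n": [99, 34],
      "mean": [-0.02437382, 0.30162732],
      "median": [-0.07788242, 0.1619777]
    },
    "rank_sum_p": 0.24898733
  },
  "signal": {
    "pearson_r": 0.7005925,
    "decile_logcpm": {
      "decile": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10],
      "n": [14, 13, 13, 13, 14, 13, 13, 13, 13, 14],
      "median": [10.81333501, 10.99996571, 11.84126693, 11.96233639, 11.94959184, 12.34415303, 13.08652853, 13.11842498, 13.37943274, 13.72651717]
    },
    "speckle_threshold": 4.65454703,
    "n_speckle_associated": 24
  },
  "pileup": {
    "specific": {
      "n_used": 38,
      "n_dropped_edge": 0,
      "n_dropped_blacklist": 2,
      "n_dropped_dedup": 0,
      "center_log2_oe": {},
      "mean_window_log2_oe": 0.00378365,
      "max_window_log2_oe": 0.2021086
    },
    "highly": {
      "n_used": 22,
      "n_dropped_edge": 0,
      "n_dropped_blacklist": 2,
      "n_dropped_dedup": 0,
      "center_log2_oe": {},
      "mean_window_log2_oe": 0.05086644,
      "max_window_log2_oe": 0.49259169
    },
    "all": {
      "n_used": 182,
      "n_dropped_edge": 9,
      "n_dropped_blacklist": 11,
      "n_dropped_dedup": 0,
      "center_log2_oe": {},
      "mean_window_log2_oe": 0.00741173,
      "max_window_log2_oe": 0.06570526
    }
  },
  "clusters": {
    "sizes": [10, 12, 8, 3],
    "ari_vs_truth": 1,
    "covariates": {
      "cluster": [1, 2, 3, 4],
      "n_genes": [10, 12, 8, 3],
      "n_peaks": [13, 15, 8, 0],
      "mean_peak_log2fc": [0.71546657, 2.89125248, 1.8195026, null],
      "mean_speckle": [1.4432606, 5.17632054, 1.44325552, 1.78756691],
      "median_speckle": [1.00571159, 4.50306374, 1.10881299, 1.53023665]
    }
  }
}
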