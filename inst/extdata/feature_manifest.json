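{
  "version": "1.0",
  "n_per_region": 100,
  "families": {
    "first_order": 19,
    "glcm": 24,
    "glrlm": 16,
    "glszm": 16,
    "ngtdm": 5,
    "ngldm": 12,
    "gabor": 8
  },
  "regions": ["intratumoral", "rim"],
  "rim_definition": "dilated-VOI value minus tumor-VOI value, 3 mm margin",
  "panel": ["fo_mean", "fo_variance", "fo_skewness", "fo_kurtosis", "fo_energy", "fo_entropy", "fo_min", "fo_max", "fo_p10", "fo_p25", "fo_median", "fo_p75", "fo_p90", "fo_iqr", "fo_range", "fo_mad", "fo_rmad", "fo_rms", "fo_uniformity", "glcm_joint_maximum", "glcm_joint_average", "glcm_joint_variance", "glcm_joint_entropy", "glcm_difference_average", "glcm_difference_variance", "glcm_difference_entropy", "glcm_sum_average", "glcm_sum_variance", "glcm_sum_entropy", "glcm_energy", "glcm_contrast", "glcm_dissimilarity", "glcm_inverse_difference", "glcm_inverse_difference_norm", "glcm_inverse_difference_moment", "glcm_inverse_difference_moment_norm", "glcm_inverse_variance", "glcm_correlation", "glcm_autocorrelation", "glcm_cluster_tendency", "glcm_cluster_shade", "glcm_cluster_prominence", "glcm_info_correlation1", "glrlm_sre", "glrlm_lre", "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle", "glrlm_lrlgle", "glrlm_lrhgle", "glrlm_gln", "glrlm_glnn", "glrlm_rln", "glrlm_rlnn", "glrlm_rp", "glrlm_glv", "glrlm_rlv", "glrlm_re", "glszm_sae", "glszm_lae", "glszm_lglze", "glszm_hglze", "glszm_salgle", "glszm_sahgle", "glszm_lalgle", "glszm_lahgle", "glszm_gln", "glszm_glnn", "glszm_szn", "glszm_sznn", "glszm_zp", "glszm_glv", "glszm_zv", "glszm_ze", "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness", "ngtdm_complexity", "ngtdm_strength", "ngldm_sde", "ngldm_lde", "ngldm_lgle", "ngldm_hgle", "ngldm_sdlgle", "ngldm_sdhgle", "ngldm_ldlgle", "ngldm_ldhgle", "ngldm_gln", "ngldm_dn", "ngldm_dnn", "ngldm_de", "gabor_o0_w4", "gabor_o45_w4", "gabor_o90_w4", "gabor_o135_w4", "gabor_o0_w8", "gabor_o45_w8", "gabor_o90_w8", "gabor_o135_w8"]
}
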