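# Default synthetic-cohort specification.
#
# Prevalences are the published per-group marginal positivity rates of the
# immunophenotype and genetic comparison tables (fractions of the
# known-value denominators).  Group sizes default to the study cohort.
n_hgbl: 121
n_ball: 47
seed: 1
prevalence:
  HGBL:
    cd45_gt_granulocytes: 0.75   # CD45 intensity above granulocytes, 72/96
    cd10_not_bright: 0.86        # CD10 below hematogone level, 83/96
    cd20_ge_mature_b: 0.72       # CD20 at/above mature B cells, 47/65
    cd38_bright: 0.70            # CD38 at hematogone level, 67/96
    tdt_negative: 0.83           # TdT negative, either modality, 72/87
    cd34_positive: 0.00          # 0/96
    surface_light_chain_monotypic: 0.75  # 72/96
    myeloid_markers_positive: 0.00       # 0/30
    myc_ihc_positive: 0.84       # MYC IHC >= 40%, 78/93
    bcl2_ihc_positive: 0.85      # BCL2 IHC >= 50%, 98/115
    bcl6_ihc_positive: 0.77      # BCL6 IHC >= 30%, 84/109
    myc_r: 0.72                  # MYC rearrangement, 87/121
    bcl2_r: 0.51
    bcl6_r: 0.22
    ccnd1_r: 0.00
    complex_karyotype: 0.93      # 53/57
    ball_translocation: 0.00     # 0/57
    tp53_mut: 0.44               # 11/25
    kras_mut: 0.00
    nras_mut: 0.00
    history_nhl: 0.33            # 40/121
    bone_marrow_site: 0.31       # 37/121
  BALL:
    cd45_gt_granulocytes: 0.23   # 11/47
    cd10_not_bright: 0.58        # 27/47
    cd20_ge_mature_b: 0.11       # 5/46
    cd38_bright: 0.38            # 18/47
    tdt_negative: 0.11           # 5/45
    cd34_positive: 0.47          # 22/47
    surface_light_chain_monotypic: 0.00  # 0/5
    myeloid_markers_positive: 0.41       # 19/46
    myc_ihc_positive: 0.24       # 9/37
    bcl2_ihc_positive: 1.00      # 7/7
    bcl6_ihc_positive: 0.16      # 6/37
    myc_r: 0.00                  # 0/44
    bcl2_r: 0.00
    bcl6_r: 0.00
    ccnd1_r: 0.00
    complex_karyotype: 0.46      # 19/41
    ball_translocation: 0.57     # 27/47
    tp53_mut: 0.15               # 6/41
    kras_mut: 0.17               # 7/41
    nras_mut: 0.22               # 9/41
    history_nhl: 0.00
    bone_marrow_site: 1.00
atypical_fraction:
  HGBL: 0.0
  BALL: 0.0
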