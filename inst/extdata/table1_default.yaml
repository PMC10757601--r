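settings:
  discount_rate_cost: 0.03
  discount_rate_outcome: 0.03
  entry_age: 45
  terminal_age: 100
  wtp: 5000.0
  currency_conversion: 32.0
  visits_per_year:
    active: 12.0
    post: 4.0
    well: 1.0
parameters:
- name: p_detect
  mean: 0.186
  se: 0.0186
  family: beta
  role: probability
- name: p_vus
  mean: 0.0631
  se: 0.0063
  family: beta
  role: probability
- name: p_family_uptake
  mean: 0.1643
  se: 0.0164
  family: beta
  role: probability
- name: p_family_positive
  mean: 0.5
  se: 0.0
  family: fixed
  role: probability
- name: p_uptake_both
  mean: 0.1897
  se: 0.019
  family: beta
  role: probability
- name: p_uptake_rrm
  mean: 0.1034
  se: 0.0103
  family: beta
  role: probability
- name: p_uptake_rrso
  mean: 0.1897
  se: 0.019
  family: beta
  role: probability
- name: p_fam_uptake_both
  mean: 0.0
  se: 0.0
  family: fixed
  role: probability
- name: p_fam_uptake_rrm
  mean: 0.0
  se: 0.0
  family: fixed
  role: probability
- name: p_fam_uptake_rrso
  mean: 0.2727
  se: 0.0273
  family: beta
  role: probability
- name: bc_dev_surv
  mean: 0.0364
  se: 0.00364
  family: beta
  role: probability
- name: bc_dev_both
  mean: 0.0037
  se: 0.00037
  family: beta
  role: probability
- name: bc_dev_rrm
  mean: 0.0072
  se: 0.00072
  family: beta
  role: probability
- name: bc_dev_rrso
  mean: 0.0178
  se: 0.00026
  family: beta
  role: probability
- name: bc_dev_neg
  mean: 0.0072
  se: 0.00072
  family: beta
  role: probability
- name: oc_dev_surv
  mean: 0.0128
  se: 0.01282
  family: beta
  role: probability
- name: oc_dev_both
  mean: 0.0018
  se: 0.00065
  family: beta
  role: probability
- name: oc_dev_rrm
  mean: 0.0036
  se: 5.0e-05
  family: beta
  role: probability
- name: oc_dev_rrso
  mean: 0.0027
  se: 0.00059
  family: beta
  role: probability
- name: oc_dev_neg
  mean: 0.0006
  se: 0.00062
  family: beta
  role: probability
- name: p_met
  mean: 0.0211
  se: 0.0021
  family: beta
  role: probability
- name: rec_1_5
  mean: 0.2432
  se: 0.0243
  family: beta
  role: probability
- name: rec_6_10
  mean: 0.0749
  se: 0.0075
  family: beta
  role: probability
- name: rec_11_15
  mean: 0.0383
  se: 0.0038
  family: beta
  role: probability
- name: rec_16p
  mean: 0.0445
  se: 0.0045
  family: beta
  role: probability
- name: oc_in_bc
  mean: 0.0007
  se: 0.0001
  family: beta
  role: probability
- name: bc_in_oc
  mean: 0.004
  se: 0.0004
  family: beta
  role: probability
- name: mort_bc_1
  mean: 0.15
  se: 0.023
  family: beta
  role: probability
- name: mort_bc_2_3
  mean: 0.1391
  se: 0.0383
  family: beta
  role: probability
- name: mort_bc_4_5
  mean: 0.1091
  se: 0.0383
  family: beta
  role: probability
- name: mort_bc_6_10
  mean: 0.0758
  se: 0.0076
  family: beta
  role: probability
- name: mort_bc_11_15
  mean: 0.039
  se: 0.0039
  family: beta
  role: probability
- name: mort_bc_16p
  mean: 0.0465
  se: 0.0047
  family: beta
  role: probability
- name: mort_brov_1_5
  mean: 0.0195
  se: 0.051
  family: beta
  role: probability
- name: mort_brov_6p
  mean: 0.0069
  se: 0.0612
  family: beta
  role: probability
- name: mort_oc_1_5
  mean: 0.0195
  se: 0.0
  family: fixed
  role: probability
- name: mort_oc_6p
  mean: 0.0069
  se: 0.0
  family: fixed
  role: probability
- name: p_met_oc
  mean: 0.0211
  se: 0.0
  family: fixed
  role: probability
- name: cost_test_ngs
  mean: 666.88
  se: 133.375
  family: gamma
  role: cost
- name: cost_test_targeted
  mean: 78.13
  se: 78.125
  family: gamma
  role: cost
- name: cost_op_bc
  mean: 902.31
  se: 2310.5
  family: gamma
  role: cost
- name: cost_op_postbc
  mean: 350.13
  se: 1258.5
  family: gamma
  role: cost
- name: cost_op_metbc
  mean: 1824.5
  se: 4539.344
  family: gamma
  role: cost
- name: cost_op_brov
  mean: 1331.81
  se: 3106.219
  family: gamma
  role: cost
- name: cost_op_oc
  mean: 448.63
  se: 1153.69
  family: gamma
  role: cost
- name: cost_op_postoc
  mean: 199.78
  se: 954.56
  family: gamma
  role: cost
- name: cost_op_metoc
  mean: 1193.22
  se: 2688.53
  family: gamma
  role: cost
- name: cost_ip_bc
  mean: 2354.44
  se: 2527.09
  family: gamma
  role: cost
- name: cost_ip_postbc
  mean: 2289.41
  se: 3615.91
  family: gamma
  role: cost
- name: cost_ip_metbc
  mean: 3469.19
  se: 5828.94
  family: gamma
  role: cost
- name: cost_ip_brov
  mean: 3533.81
  se: 4247.16
  family: gamma
  role: cost
- name: cost_ip_oc
  mean: 2543.5
  se: 1648.91
  family: gamma
  role: cost
- name: cost_ip_postoc
  mean: 2515.59
  se: 2139.38
  family: gamma
  role: cost
- name: cost_ip_metoc
  mean: 4087.28
  se: 5087.0
  family: gamma
  role: cost
- name: cost_visit_transport
  mean: 17.0
  se: 27.97
  family: gamma
  role: cost
- name: cost_visit_meal
  mean: 3.97
  se: 8.94
  family: gamma
  role: cost
- name: cost_visit_accom
  mean: 3.22
  se: 21.97
  family: gamma
  role: cost
- name: cost_visit_opportunity
  mean: 19.53
  se: 43.38
  family: gamma
  role: cost
- name: cost_fy_well
  mean: 126.19
  se: 321.28
  family: gamma
  role: cost
- name: cost_fy_bc
  mean: 282.72
  se: 1201.28
  family: gamma
  role: cost
- name: cost_fy_postbc
  mean: 3.13
  se: 10.16
  family: gamma
  role: cost
- name: cost_fy_metbc
  mean: 209.59
  se: 631.13
  family: gamma
  role: cost
- name: cost_fy_brov
  mean: 96.88
  se: 247.56
  family: gamma
  role: cost
- name: cost_fy_oc
  mean: 97.09
  se: 130.09
  family: gamma
  role: cost
- name: cost_fy_postoc
  mean: 5.22
  se: 15.63
  family: gamma
  role: cost
- name: cost_fy_metoc
  mean: 260.41
  se: 247.56
  family: gamma
  role: cost
- name: cost_rec_bc
  mean: 1289.56
  se: 2359.03
  family: gamma
  role: cost
- name: cost_rec_postbc
  mean: 466.47
  se: 1609.0
  family: gamma
  role: cost
- name: cost_rec_metbc
  mean: 1980.34
  se: 3954.06
  family: gamma
  role: cost
- name: cost_rec_brov
  mean: 992.5
  se: 2025.72
  family: gamma
  role: cost
- name: cost_rec_oc
  mean: 756.78
  se: 1469.97
  family: gamma
  role: cost
- name: cost_rec_postoc
  mean: 223.78
  se: 373.06
  family: gamma
  role: cost
- name: cost_rec_metoc
  mean: 3250.0
  se: 5629.16
  family: gamma
  role: cost
- name: cost_rrm
  mean: 1239.0
  se: 0.0
  family: fixed
  role: cost
- name: cost_rrso
  mean: 631.0
  se: 0.0
  family: fixed
  role: cost
- name: u_well
  mean: 0.89
  se: 0.13
  family: beta
  role: utility
- name: u_bc
  mean: 0.84
  se: 0.18
  family: beta
  role: utility
- name: u_postbc
  mean: 0.9
  se: 0.09
  family: beta
  role: utility
- name: u_metbc
  mean: 0.8
  se: 0.16
  family: beta
  role: utility
- name: u_brov
  mean: 0.86
  se: 0.11
  family: beta
  role: utility
- name: u_oc
  mean: 0.76
  se: 0.18
  family: beta
  role: utility
- name: u_postoc
  mean: 0.88
  se: 0.13
  family: beta
  role: utility
- name: u_metoc
  mean: 0.71
  se: 0.39
  family: beta
  role: utility
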