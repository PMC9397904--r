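# clock model kinetic parameters
# units: rates per hour; concentrations and Michaelis constants in a.u.;
#        light coupling per hour per light a.u.
name	value
bas_wcc	0.3
vmax_l_wcc	1
K_l_wcc	2.5
bas_frq	0.02
vmax_d_frq	1.97
K_d_frq	4
vmax_l_frq	48.31
K_l_frq	0.02778
bas_vvd	0.2859
vmax_d_vvd	3
K_d_vvd	15
vmax_l_vvd	269.3
K_l_vvd	0.2946
bas_csp1	0.03
vmax_d_csp1	1.2
K_d_csp1	7.5
vmax_l_csp1	54.41
K_l_csp1	1.102
K_rep_csp1	1.143
bas_fam3	1
K_rep_fam3	0.2
kdm_wcc	0.25
kdm_frq	0.4
kdm_vvd	0.5
kdm_csp1	0.7563
kdm_fam3	0.25
ktl_wcc	2.5
ktl_frq	0.417
ktl_vvd	3
kmat_1	1
kmat_2	1
kmat_3	1
kmat_4	1
kmat_5	1
kdf_1	0.005
kdf_2	0.005
kdf_3	0.005
kdf_4	0.005
kdf_5	0.005
kdeg_ffc	0.25
kcat_wcc	7.5
KMp_wcc	0.8
kcat_wccs	0.05
KMp_wccs	2
kcat_wcc2s	0.05
KMp_wcc2s	2
kcat_wccvvds	0.05
KMp_wccvvds	2
kd2	0.18
klight_wcc	10
klight_vvd	100
krev_wccs	0.3
krev_vvds	0.2886
krev_wcc2s	0.3
krev_wccvvds	0.35
kon_ww	2
koff_ww	1
kon_wv	4.051
koff_wv	2.522
kdeg_wcc	0.05
kdeg_pwcc	0.01
kdeg_wccs	1
kdeg_wcc2s	0.4
kdeg_wccvvds	0.235
kdeg_vvd	0.25
kdeg_vvds	4.107
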