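# axonmem force field (reduced units: sigma, eps, t_s)
units.sigma_nm = 2.2272467953508484
units.kBT_over_eps = 0.22
forcefield.k0 = 6.5
forcefield.req_ss = 2.244924096618746
forcefield.eps1 = 0.46000000000000002
forcefield.kA = 69.349999999999994
forcefield.req_aa = 15.71446867633122
forcefield.kb = 770
forcefield.theta0 = 2.9804853380210861
forcefield.dthmax = 0.89414560140632571
forcefield.eps2 = 7.2999999999999998
forcefield.scale_as = 8
forcefield.capture_as = 20
forcefield.kmt = 52.579999999999998
forcefield.deq_rr = 83.062191574893603
forcefield.ddmax = 24.91865747246808
forcefield.rcut_mem = 2.6000000000000001
forcefield.alpha = 1.55
forcefield.k_ll = 1.2
forcefield.k_lprot = 2.7999999999999998
forcefield.req_ll = 1.122462048309373
forcefield.req_lg = 1.6836930724640593
forcefield.req_lp = 1.6836930724640593
forcefield.req_pp = 2.244924096618746
forcefield.k_layer = 0.01
forcefield.wc = 1.3774999999999999
forcefield.rcut_layer = 1.122462048309373
forcefield.n_sl = 0
forcefield.scale_sl = 1.5
forcefield.rcut_sl = 3.75
forcefield.req_sk = 6.7347722898562372
forcefield.req_ag = 8.9796963864749841
forcefield.eps_steric = 0.46000000000000002
forcefield.skin = 0.40000000000000002
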