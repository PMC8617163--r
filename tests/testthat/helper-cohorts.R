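# shared fixtures, built once per test run

# default-condition cohort used by several files
shared_cohort <- generate_cohort("SN60WF", n = 265, seed = 1)

# noise-free, quantization-free cohort (round-trip checks)
clean_cohort <- function(n = 120, seed = 3, gt_kind = "linear",
                         pc_transform = "mean_k", gt = NULL) {
  generate_cohort("SN60WF", n = n, gt_kind = gt_kind, seed = seed,
                  gt = if (is.null(gt))
                    ground_truth_elp(gt_kind, elp_noise_sd = 0) else gt,
                  noise = noise_model(0, 0, 0),
                  pc_transform = pc_transform)
}

# random valid optics inputs on physiological grids
random_optics_inputs <- function(n, seed) {
  set.seed(seed)
  data.frame(al = runif(n, 20, 30),
             elp = runif(n, 3, 7),
             pc = runif(n, 38, 48),
             rx = runif(n, -3, 3))
}
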