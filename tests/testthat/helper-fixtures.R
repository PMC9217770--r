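# shared fixture builders for the test suite

# random differential DVH on a uniform grid
random_dvh <- function(n_bins = 50, bin_width = 0.1, organ = "thyroid",
                       max_vol = 10) {
  dvh_differential(organ, bin_width * (0:n_bins),
                   stats::runif(n_bins, 0, max_vol))
}

# smooth gamma-shaped DVH used for grid-refinement checks
smooth_dvh <- function(bin_width, organ = "lung_ipsilateral",
                       total = 1400, dmax = 30) {
  edges <- seq(0, dmax, by = bin_width)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- stats::dgamma(ctr, shape = 1.8, scale = 2.5)
  dvh_differential(organ, edges, dens * total / sum(dens))
}

# one complete six-organ patient with simple deterministic DVHs
fixture_patient <- function(id = "P1", group = "PBI_CTL") {
  mk <- function(o, vols) dvh_differential(o, 0:length(vols), vols)
  ipsi <- mk("lung_ipsilateral", c(400, 600, 300, 100))
  contra <- mk("lung_contralateral", c(1000, 300, 100))
  patient_record(id, group, list(
    breast_contralateral = mk("breast_contralateral", c(300, 200, 80, 20)),
    lungs_both = combine_dvh(ipsi, contra, "lungs_both"),
    lung_ipsilateral = ipsi,
    lung_contralateral = contra,
    thyroid = mk("thyroid", c(12, 6, 2)),
    esophagus = mk("esophagus", c(20, 10, 5))))
}

# voxel-sampling Monte-Carlo oracle for the OED: draw voxels from the DVH
# and average the kernel over them; returns estimate and its standard error
oed_mc_oracle <- function(d, model, n = 1e6) {
  ctr <- bin_centers(d)
  idx <- sample.int(length(ctr), n, replace = TRUE,
                    prob = d$bin_volumes / d$total_volume)
  r <- red(ctr[idx], model)
  list(estimate = mean(r), se = stats::sd(r) / sqrt(n))
}
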