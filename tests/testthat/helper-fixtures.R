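# Shared fixtures, computed once per test run and cached.
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache))
    assign(name, expr, envir = fixture_cache)
  get(name, envir = fixture_cache)
}

small_config <- function(seed = 42, n_snp_probes = 40,
                         contamination = c(0.05, 0.5), snp_noise_sd = 0.02,
                         delta_beta = 0.5) {
  sim_config(n_classes = 4, samples_per_class = 8, n_probes = 600,
             informative_per_class = 30, n_lump_probes = 40,
             n_snp_probes = n_snp_probes, n_reference = 4, seed = seed,
             contamination = contamination, snp_noise_sd = snp_noise_sd,
             delta_beta = delta_beta)
}

small_cohort <- function() cached("small_cohort",
                                  simulate_cohort(small_config()))

# study-condition fixture for deconvolution recovery:
# k = 5 components (4 tumor classes + leukocyte), 2,000 probes, 120 tumor
# samples, beta noise 0.02
deconv_config <- function() {
  sim_config(n_classes = 4, samples_per_class = 30, n_probes = 2000,
             informative_per_class = 100, n_lump_probes = 80,
             n_snp_probes = 20, n_reference = 4, noise_sd = 0.02, seed = 11)
}

deconv_cohort <- function() cached("deconv_cohort",
                                   simulate_cohort(deconv_config()))

deconv_fit <- function() cached("deconv_fit", {
  coh <- deconv_cohort()
  tumor <- coh$sample_sheet$sample_id[coh$sample_sheet$specimen == "tumor"]
  cpg <- coh$manifest$probe_id[coh$manifest$probe_class == "cpg"]
  fit_deconvolution(coh$beta[cpg, tumor], k = 5, lambda = 0.01,
                    n_restarts = 10, seed = 11)
})

# study-condition fixture for classification: 8 classes x 20 samples,
# 400 informative CpGs, contamination active
classify_cohort <- function() cached("classify_cohort",
                                     simulate_cohort(sim_config(seed = 7)))

classify_reference <- function() cached("classify_reference",
  run_build_reference(classify_cohort(), k = 9, lambda = 0.01,
                      feature_n = 2000, n_restarts = 5, seed = 7))

tumor_ids <- function(cohort)
  cohort$sample_sheet$sample_id[cohort$sample_sheet$specimen == "tumor"]

cpg_ids <- function(cohort)
  cohort$manifest$probe_id[cohort$manifest$probe_class == "cpg"]
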