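# Shared fixtures, computed lazily and cached for the whole test run.

.fix_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fix_env)) {
    assign(name, force(expr), envir = .fix_env)
  }
  get(name, envir = .fix_env)
}

adult_phys <- function() cached("adult_phys", load_physiology("adult"))
adult_drug <- function() cached("adult_drug", default_drug_params())

# the eleven structural estimates of the bundled adult model
truth_vector <- function() {
  d <- adult_drug()
  c(kp_lung = d$kp[["lung"]], kp_heart = d$kp[["heart"]],
    ps_heart = d$ps[["heart"]], kp_kidney = d$kp[["kidney"]],
    ps_kidney = d$ps[["kidney"]], kp_liver = d$kp[["liver"]],
    kp_thyroid = d$kp[["thyroid"]], kp_other = d$kp[["other"]],
    cl_renal = d$cl[["renal"]], cl_liver = d$cl[["liver"]],
    k_gb = d$k_gb)[fitted_parameters()]
}

zero_sigma <- function() {
  stats::setNames(rep(0, length(observable_tissues())), observable_tissues())
}

noise_free_dataset <- function() {
  cached("noise_free_dataset",
         generate_dataset(synthetic_spec(sigma = zero_sigma(), seed = 7),
                          adult_phys(), adult_drug()))
}

# closed-loop refit of the noise-free dataset from a perturbed start
noise_free_fit <- function() {
  cached("noise_free_fit", {
    init <- truth_vector() * rep(c(1.5, 0.67), length.out = 11)
    fit_closed_loop(noise_free_dataset(), adult_phys(), init = init,
                    drug = adult_drug())
  })
}

default_study <- function() cached("default_study", dosimetry_study())
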