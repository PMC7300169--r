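## Pinned synthetic cohort used by the qualitative regression tests.
pinned_cohort <- function(seed = 20200617L) {
  sample_cohort(cohort_config(seed = seed))
}

## A patient with pure mono-exponential kinetics (instantaneous uptake),
## for which the planar and hybrid estimators are exact in the noiseless
## limit. teff = c(kidney, lesion1, lesion2) effective half-lives in hours.
mono_patient <- function(id = 1L, A0 = 7300, teff = c(40, 50, 60),
                         C = c(150, 40, 15)) {
  lphys <- lu177_lambda_phys()
  kin <- function(te, amp) {
    region_kinetics(C = amp, lambda_bio = log(2) / te - lphys,
                    lambda_up = Inf)
  }
  structure(list(patient_id = as.integer(id), A0 = A0,
                 kidney = kin(teff[1], C[1]),
                 lesions = list(kin(teff[2], C[2]), kin(teff[3], C[3]))),
            class = "virtual_patient")
}

mono_cohort <- function(n = 1L, ...) {
  structure(lapply(seq_len(n), function(i) mono_patient(id = i, ...)),
            class = "virtual_cohort")
}
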