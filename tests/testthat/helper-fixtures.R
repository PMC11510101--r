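# Shared fixture builders (everything generated in code; no stored data).

# founder pair with one offspring
trio_ped <- function() {
  data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
             dam = c(NA, NA, "d"), stringsAsFactors = FALSE)
}

# full-sib mating: z is the offspring of full sibs x and y (F = 0.25)
fullsib_mating_ped <- function() {
  data.frame(id = c("s", "d", "x", "y", "z"),
             sire = c(NA, NA, "s", "s", "x"),
             dam = c(NA, NA, "d", "d", "y"), stringsAsFactors = FALSE)
}

# 6-animal pedigree with a genotyped subset, used for H fixtures
six_ped <- function() {
  data.frame(id = as.character(1:6), sire = c(NA, NA, "1", "1", "3", "5"),
             dam = c(NA, NA, "2", "2", "4", "4"), stringsAsFactors = FALSE)
}

# small random herd pedigree
small_herd_ped <- function(n_off = 30, n_dams = 8, n_sires = 4, seed = 1) {
  simulate_pedigree(herd_design(n_dams = n_dams, n_sires = n_sires,
                                n_offspring = n_off, n_genotyped = 0,
                                n_with_microbiota = 0), seed = seed)
}

# growth records satisfying FI = mu + alpha*midBW^0.75 + beta*ADG exactly
exact_rfi_records <- function(mu = 10, alpha = 0.1, beta = 2) {
  bw_start <- c(800, 850, 900, 950, 1000)
  bw_end <- c(2000, 2120, 2260, 2380, 2555)
  days <- 35
  adg <- (bw_end - bw_start) / days
  midbw75 <- ((bw_start + bw_end) / 2)^0.75
  fi_daily <- mu + alpha * midbw75 + beta * adg
  data.frame(animal_id = paste0("a", 1:5), bw_start = bw_start,
             bw_end = bw_end, days = days,
             feed_intake_total = fi_daily * days, stringsAsFactors = FALSE)
}

# synthetic reml_fit object for arithmetic-only checks
fake_fit <- function(theta, loglik = -100, ai = NULL, model = NULL) {
  k <- length(theta)
  if (is.null(ai)) ai <- diag(0.01, k)
  dimnames(ai) <- list(names(theta), names(theta))
  structure(list(theta = theta, se = sqrt(diag(ai)), ai_inverse = ai,
                 loglik = loglik, n = 100, rank_X = 1, n_params = k,
                 converged = TRUE, iterations = 5,
                 boundary = stats::setNames(rep(FALSE, k), names(theta)),
                 gradient_norm = 0, model = model),
            class = "reml_fit")
}
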