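# internal helpers shared across modules

# deterministic fan-out of one user seed into per-stage seeds; keeps stages
# reproducible independently of how many random draws earlier stages consume
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    pedigree = 101L, haplotypes = 211L, genedrop = 307L, metabolome = 401L,
    mqtl = 503L, noise = 601L, kp = 701L, impute = 809L, misc = 907L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# numeric matrix of metabolite columns of a samples-by-metabolites tibble;
# every column that is not sample_id/plate is treated as a metabolite
met_matrix <- function(data) {
  ids <- metabolite_ids(data)
  m <- as.matrix(data[ids])
  if (!is.numeric(m)) {
    bad <- ids[!vapply(data[ids], is.numeric, logical(1))]
    abort(paste0("non-numeric metabolite column(s): ", toString(bad)))
  }
  rownames(m) <- data$sample_id
  m
}

metabolite_ids <- function(data) {
  setdiff(names(data), c("sample_id", "plate", "is_pool"))
}

# rebuild the tibble around a (possibly filtered) value matrix
rebuild_met <- function(data, values, keep_samples = data$sample_id) {
  idx <- match(keep_samples, data$sample_id)
  out <- tibble(sample_id = keep_samples)
  if ("plate" %in% names(data)) out$plate <- data$plate[idx]
  if ("is_pool" %in% names(data)) out$is_pool <- data$is_pool[idx]
  dplyr::bind_cols(out, as_tibble(values))
}

`%||%` <- rlang::`%||%`
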