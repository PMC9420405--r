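# Small deterministic fixtures built in code.

# a hand-written 5-specimen dataset with round measurement values
tiny_dataset <- function() {
  df <- data.frame(
    specimen_id = paste0("sp", 1:5),
    taxon = c("A", "A", "A", "B", "B"),
    group = c("g1", "g1", "g1", "g2", "g2"),
    age_class = c("adult", "adult", "juvenile", "adult", "juvenile"),
    GOL = c(150, 160, 120, 180, 140),
    BBH = c(100, 105, 90, 115, 95),
    XCB = c(120, 125, 100, 135, 110),
    NPH = c(70, 75, 50, 85, 60),
    BPL = c(100, 108, 70, 120, 82),
    ZYB = c(125, 130, 100, 140, 110),
    bm_kg = c(50, 55, NA, 70, NA),
    ecv_cm3 = c(400, 420, 300, 500, 350),
    geo_age = NA_real_
  )
  cranio_dataset(df)
}

# dataset wrapper around an arbitrary measurement matrix
matrix_dataset <- function(mm, group = "g", age_class = "adult") {
  mm <- as.matrix(mm)
  colnames(mm) <- cranio_vars()
  df <- data.frame(specimen_id = paste0("m", seq_len(nrow(mm))),
                   taxon = "t", group = group,
                   age_class = rep_len(age_class, nrow(mm)), mm)
  cranio_dataset(df)
}

meas <- function(ds) {
  m <- as.matrix(as.data.frame(ds)[, cranio_vars()])
  rownames(m) <- ds$specimen_id
  m
}

# random positive measurement rows on a realistic scale
random_dataset <- function(n, seed) {
  set.seed(seed)
  mm <- matrix(10^(stats::rnorm(n * 6, mean = 2, sd = 0.15)), n, 6)
  matrix_dataset(mm)
}

# the two-group transposed generator config used in parameter-recovery
# checks: shared allometry, group 2 shifted toward a relatively larger
# neurocranium
two_group_config <- function(n_per_stage = 50, noise_sd = 0.01, seed = 1,
                             b = c(0.8, 0.8, 0.8, 1.2, 1.2, 1.2),
                             delta = 0.1) {
  base <- c(1.4, 1.4, 1.4, -0.4, -0.4, -0.4)
  groups <- list(
    synthetic_group("anc", n_per_stage, n_per_stage, base, 2.1,
                    size_mean_juvenile = 1.95, size_sd = 0.05),
    synthetic_group("desc", n_per_stage, n_per_stage,
                    base + delta * c(1, 1, 1, -1, -1, -1), 2.1,
                    size_mean_juvenile = 1.95, size_sd = 0.05)
  )
  synthetic_config(groups, allometry = b, noise_sd = noise_sd, seed = seed)
}
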