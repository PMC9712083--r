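# Small hand-built fixtures used across test files.

make_bones <- function(age = c(2000, 1000, 500),
                       mat = c(-20, -5, 10),
                       burial_class = rep("never_buried", length(age)),
                       region = paste0("reg_", seq_along(age)),
                       age_2sigma = rep(40, length(age))) {
  tibble::tibble(
    record_id = sprintf("b%02d", seq_along(age)),
    region = region,
    taxon = "test_taxon",
    age = age,
    age_2sigma = age_2sigma,
    mat = mat,
    burial_class = burial_class
  )
}

make_occurrences <- function(age, source = "fossil", region = "reg_A",
                             age_2sigma = rep(0, length(age))) {
  tibble::tibble(
    record_id = sprintf("o%03d", seq_along(age)),
    region = region,
    source = rep_len(source, length(age)),
    age = age,
    age_2sigma = age_2sigma
  )
}

# Bones whose log10(age) is exactly linear in MAT (residual variance 0).
make_collinear_bones <- function(slope = -0.05, intercept = 3,
                                 mat = c(-10, 0, 10)) {
  make_bones(age = 10^(intercept + slope * mat), mat = mat)
}
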