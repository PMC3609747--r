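# small fixtures built in code

toy_outcomes <- function() {
  tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 4),
    device = rep(c("NYU", "NYU", "IH"), each = 4),
    group = rep(c("sham_nyu", "nyu_12.5mm", "ih_75kdyn"), each = 4),
    displacement = rep(c(NA, 1.65, 900), each = 4),
    displacement_unit = rep(c(NA, "mm", "micron"), each = 4),
    variable = rep(c("bbb", "bbb", "weight_change", "weight_change"), 3),
    variable_class = rep(c("behavioral", "behavioral", "health", "health"), 3),
    timepoint_days = rep(c(7, 14, 7, 14), 3),
    value = c(2, 4, 10, 12,   6, 8, -5, -7,   1, 3, 0, 2)
  )
}

toy_spec <- function() {
  tibble::tibble(
    variable = c("bbb", "weight_change"),
    class = c("behavioral", "health"),
    timepoints = list(c(7, 14), c(7, 14))
  )
}

# random correlation matrix via random data
random_cor <- function(p, n = 200) {
  cor(matrix(rnorm(n * p), n, p))
}

small_config <- function(seed = 1, missing_rate = 0) {
  syn_config(missing_rate = missing_rate, seed = seed)
}
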