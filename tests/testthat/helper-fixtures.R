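# shared fixture builders; everything is generated in code at test time

# one-sample toy peptide with given light/heavy areas per fragment
toy_peptide <- function(light, heavy, sample_id = "s1", peptide_key = "PEP",
                        background = 0) {
  k <- length(light)
  frags <- paste0("y", 2 + seq_len(k))
  dplyr::bind_rows(
    tibble::tibble(
      sample_id = sample_id, peptide_key = peptide_key,
      precursor_charge = 2L, fragment_ion = frags, label = "light",
      area = light, background = background
    ),
    tibble::tibble(
      sample_id = sample_id, peptide_key = peptide_key,
      precursor_charge = 2L, fragment_ion = frags, label = "heavy",
      area = heavy, background = background
    )
  )
}

# random transition table exercising missing labels, zero backgrounds and
# areas straddling the S/N limit
random_transitions <- function(seed, max_rows = 200) {
  set.seed(seed)
  n_pep <- sample(2:6, 1)
  n_samp <- sample(2:6, 1)
  rows <- list()
  for (p in seq_len(n_pep)) {
    frags <- paste0("y", 2 + seq_len(sample(2:5, 1)))
    for (s in seq_len(n_samp)) {
      for (f in frags) {
        bg <- sample(c(0, 10, 50), 1)
        heavy_area <- stats::runif(1, 0, 400)
        light_area <- stats::runif(1, 0, 400)
        lab <- sample(c("both", "light", "heavy"), 1,
                      prob = c(0.8, 0.1, 0.1))
        if (lab %in% c("both", "light")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = paste0("s", s), peptide_key = paste0("pep", p),
            precursor_charge = 2L, fragment_ion = f, label = "light",
            area = light_area, background = bg
          )
        }
        if (lab %in% c("both", "heavy")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = paste0("s", s), peptide_key = paste0("pep", p),
            precursor_charge = 2L, fragment_ion = f, label = "heavy",
            area = heavy_area, background = bg
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[seq_len(min(nrow(out), max_rows)), ]
}

# small, fast simulation settings used across tests
quick_config <- function(seed = 1, ...) {
  defaults <- list(
    n_patients = c(6L, 3L, 3L), n_targets = 40L, n_detectable = 20L,
    effects = c("ERK2 (T185)" = 1.1, "FAK (Y576)" = -0.6),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

record_key <- function(x) {
  paste(x$sample_id, x$peptide_key, x$precursor_charge, x$fragment_ion,
        x$label, sep = "|")
}

expect_same_records <- function(a, b) {
  expect_setequal(record_key(a), record_key(b))
  a <- a[order(record_key(a)), ]
  b <- b[order(record_key(b)), ]
  expect_equal(a$area, b$area)
  expect_equal(a$background, b$background)
}
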