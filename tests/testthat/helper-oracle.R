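# literal per-record brute-force implementations of every filter rule,
# written as plain loops, independent of the package internals

oracle_snr <- function(records, config) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- records$area[i]
    b <- records$background[i]
    keep[i] <- if (b == 0) a > 0 else !(a < config$snr_min * b)
  }
  records[keep, ]
}

oracle_contribution <- function(records, config) {
  keep <- rep(TRUE, nrow(records))
  groups <- unique(records[c("sample_id", "peptide_key", "precursor_charge")])
  for (g in seq_len(nrow(groups))) {
    in_g <- records$sample_id == groups$sample_id[g] &
      records$peptide_key == groups$peptide_key[g] &
      records$precursor_charge == groups$precursor_charge[g]
    light_idx <- which(in_g & records$label == "light")
    heavy_idx <- which(in_g & records$label == "heavy")
    light_sum <- sum(records$area[light_idx])
    heavy_sum <- sum(records$area[heavy_idx])
    for (i in light_idx) {
      j <- heavy_idx[records$fragment_ion[heavy_idx] ==
                       records$fragment_ion[i]]
      if (length(j) == 0) {
        keep[i] <- FALSE
      } else {
        cl <- records$area[i] / light_sum
        ch <- records$area[j] / heavy_sum
        if (abs(cl - ch) > config$contribution_tol) keep[i] <- FALSE
      }
    }
  }
  records[keep, ]
}

oracle_sparse <- function(records, config) {
  keep <- rep(TRUE, nrow(records))
  groups <- unique(records[c("sample_id", "peptide_key")])
  detected <- character()
  for (g in seq_len(nrow(groups))) {
    in_g <- records$sample_id == groups$sample_id[g] &
      records$peptide_key == groups$peptide_key[g]
    n_light <- length(unique(
      records$fragment_ion[in_g & records$label == "light"]
    ))
    if (n_light < config$min_transitions) {
      keep[in_g] <- FALSE
    } else {
      detected <- c(detected, groups$peptide_key[g])
    }
  }
  for (pep in unique(records$peptide_key)) {
    if (sum(detected == pep) < config$min_files) {
      keep[records$peptide_key == pep] <- FALSE
    }
  }
  records[keep, ]
}

oracle_select <- function(records, config) {
  out <- list()
  for (pep in sort(unique(records$peptide_key))) {
    rp <- records[records$peptide_key == pep, ]
    frags <- sort(unique(rp$fragment_ion))
    devs <- stats::setNames(lapply(frags, function(f) numeric()), frags)
    for (s in unique(rp$sample_id)) {
      rs <- rp[rp$sample_id == s, ]
      ratios <- c()
      for (f in frags) {
        li <- rs$area[rs$fragment_ion == f & rs$label == "light"]
        hi <- rs$area[rs$fragment_ion == f & rs$label == "heavy"]
        if (length(li) == 1 && length(hi) == 1 && li > 0 && hi > 0) {
          ratios[f] <- log2(li / hi)
        }
      }
      if (length(ratios) == 0) next
      ref <- stats::median(ratios)
      for (f in names(ratios)) {
        devs[[f]] <- c(devs[[f]], abs(ratios[f] - ref))
      }
    }
    consistent <- frags[vapply(
      frags,
      function(f) length(devs[[f]]) > 0 &&
        mean(devs[[f]]) <= config$ratio_consistency_tol,
      logical(1)
    )]
    if (length(consistent) >= config$min_transitions) {
      out[[pep]] <- tibble::tibble(peptide_key = pep,
                                   fragment_ion = consistent)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(peptide_key = character(),
                          fragment_ion = character()))
  }
  dplyr::bind_rows(out)
}
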