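# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized lattice search: the enumeration oracle is a plain
# recursive depth-first walk over the bounded count lattice.

residue_masses <- glyco_masses()$residues

# brute-force enumeration of all (composition, adduct) pairs matching mz
# within tolerance; returns species keys (composition + adduct strings)
oracle_enumerate <- function(mz, mode, max_counts, adduct_labels,
                             tol_ppm = NULL, tol_da = NULL) {
  hits <- character(0)
  shift_of <- function(lab) {
    ad <- parse_adduct_label(lab)
    m <- glyco_masses()
    list(shift = ad[["Na"]] * m$sodium + ad[["K"]] * m$potassium +
           (ad[["H"]] - ad[["H_removed"]]) * m$proton,
         z = abs(ad[["H"]] + ad[["Na"]] + ad[["K"]] - ad[["H_removed"]]))
  }
  res_names <- names(residue_masses)
  walk <- function(i, counts) {
    if (i > length(res_names)) {
      if (sum(counts[setdiff(res_names, "S")]) == 0) return()
      M <- sum(counts * residue_masses) + glyco_masses()$water
      for (lab in adduct_labels) {
        if (adduct_mode(lab) != mode) next
        s <- shift_of(lab)
        theo <- (M + s$shift) / s$z
        ok <- if (!is.null(tol_da)) abs(theo - mz) <= tol_da
              else abs(1e6 * (mz - theo) / theo) <= tol_ppm
        if (ok) {
          comp <- do.call(glycan_composition, as.list(counts))
          hits <<- c(hits, paste(format_composition(comp), lab))
        }
      }
      return()
    }
    for (k in 0:max_counts[[res_names[i]]]) {
      counts[res_names[i]] <- k
      walk(i + 1, counts)
    }
  }
  walk(1, stats::setNames(integer(length(res_names)), res_names))
  sort(hits)
}

# random valid composition within small bounds
random_composition <- function(max_each = 4) {
  repeat {
    counts <- c(Hex = sample(0:max_each, 1), HexNAc = sample(0:max_each, 1),
                Fuc = sample(0:2, 1), Neu5Ac = sample(0:2, 1),
                Neu5Gc = sample(0:2, 1), S = sample(0:1, 1))
    if (sum(counts[c("Hex", "HexNAc", "Fuc", "Neu5Ac", "Neu5Gc")]) > 0) {
      return(do.call(glycan_composition, as.list(counts)))
    }
  }
}

# simple abundance matrix fixture: 3 groups x n replicates, given values
make_matrix <- function(values_by_species, n_per_group = 3) {
  groups <- rep(group_levels(), each = n_per_group)
  ids <- sprintf("%s_%d", groups, rep(seq_len(n_per_group), times = 3))
  values <- do.call(cbind, values_by_species)
  colnames(values) <- names(values_by_species)
  rownames(values) <- ids
  abundance_matrix(values, data.frame(sample_id = ids, group = groups))
}
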