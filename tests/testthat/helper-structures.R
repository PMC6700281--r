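# Canonical example structures used across tests.
canonical42 <- function() {
  parse_structure("CAG_42 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2")
}

# A library of repeat structures spanning classes and CAG lengths, plus a
# few "other" arrangements.
structure_library <- function(cags = c(15L, 20L, 30L, 40L, 42L, 44L, 50L,
                                       55L, 60L)) {
  lib <- list()
  for (L in cags) {
    for (cls in c("canonical", "caa_loss", "caacag_dup")) {
      lib[[length(lib) + 1L]] <- hd_structure(L, cls)
    }
  }
  # rare non-canonical arrangements ("other")
  lib[[length(lib) + 1L]] <-
    parse_structure("CAG_20 CAA_2 CAG_1 CCG_7 CCT_2")
  lib[[length(lib) + 1L]] <-
    parse_structure("CAG_25 CAA_1 CAG_5 CCG_1 CCA_1 CCG_7 CCT_2")
  lib[[length(lib) + 1L]] <-
    parse_structure("CAG_18 CCG_1 CCA_1 CCG_7 CCT_2")
  lib
}

# Error-free read pair fully spanning the repeat region of `structure`.
perfect_pair <- function(structure, read_length = 300L) {
  cfg <- sim_config(seed = 1, coverage = 1L, base_error = 0,
                    read_length = read_length)
  reads <- simulate_reads(list(structure), cfg, seed = NULL)
  list(fwd = reads$fwd[1L], rev = reads$rev[1L])
}
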