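# Shared fixture builders (everything is generated in code; no stored data).

make_cell_table <- function(n = 3, behaviour = rep_len(c("ACD", "DIFF"), n)) {
  m <- pmin(2L, seq_len(n) %% 3L)
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    individual = rep("1", n),
    mother_id = c(NA_character_, sprintf("c%03d", seq_len(n - 1))),
    birth_time_min = 40 * seq_len(n),
    birth_area_um2 = 80 + 5 * seq_len(n),
    perimeter_um = 40 + seq_len(n),
    pos_x_um = 10 * seq_len(n),
    pos_y_um = 20 * seq_len(n),
    n_neighbours_total = m + 4L,
    n_sig_neighbours = m + 1L,
    n_meristemoid_nb = m,
    n_gmc_nb = rep(1L, n),
    n_stoma_nb = rep(0L, n),
    sig_contact_fraction = 0.1 * (m + 1L),
    behaviour = behaviour,
    stringsAsFactors = FALSE
  )
}

# cohort whose fate rule is strongly dominated by birth size
size_dominated_truth <- function() {
  generator_truth(model = model_spec(
    "neighbour",
    c(intercept = 7.2, size = -0.08, conc_dip = 0.01, neighbours = -0.05),
    id = "size-dominated"))
}

# sub-seed derivation used everywhere a loop needs independent seeds
sub_seed <- function(seed, i) (seed * 100 + i) %% .Machine$integer.max
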