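# shared fixtures: synthetic traces, toy schemes and synthetic PDB files

# normalized synthetic stopped-flow trace from known multi-exponential
# parameters on the standard protocol grid
synthetic_sf_trace <- function(offset, amp, rate, noise_sd = 0, seed = 1,
                               pH = 5, sensor_id = "synthetic") {
  prot <- sf_protocol()
  tt <- protocol_grid(prot)
  tt <- tt[tt >= prot$dead_time]
  y <- rep(offset, length(tt))
  for (i in seq_along(amp)) y <- y + amp[i] * exp(-rate[i] * tt)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(tt), 0, noise_sd)
  }
  structure(list(time = tt, intensity = y, pH = pH, sensor_id = sensor_id,
                 condition = "normalized", seed = seed, protocol = prot),
            class = "sf_trace")
}

# effectively 2-state scheme: R -> P irreversible with rate k at the given pH
two_state_scheme <- function(k, pH) {
  act <- function(pK, n) {
    r <- (10^(-pH) / 10^(-pK))^n
    r / (1 + r)
  }
  gating_scheme(steps = list(
    "R-P" = list(kmax = k / act(5, 1.5), pK = 5, n = 1.5, kback = 0),
    "P-O" = list(kmax = 0, kback = 0),
    "O-D" = list(kmax = 0, kback = 0)
  ))
}

# minimal synthetic PDB text from an atom table
write_synthetic_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    rec <- if (isTRUE(a$het)) "HETATM" else "ATOM  "
    sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, i, a$name, ifelse(is.null(a$alt) || is.na(a$alt), " ", a$alt),
            a$resid, a$chain, a$resno, a$x, a$y, a$z, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

atom_row <- function(chain, resno, resid, name, x, y, z, elem = "C",
                     het = FALSE, alt = NA) {
  data.frame(chain = chain, resno = resno, resid = resid, name = name,
             x = x, y = y, z = z, elem = elem, het = het, alt = alt,
             stringsAsFactors = FALSE)
}

# small protein-like synthetic structure: a chain of CA/CB pseudo-residues
synthetic_structure_atoms <- function(shift = c(0, 0, 0)) {
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- atom_row("A", i, "ALA", "CA",
                                         i * 3.8 + shift[1], shift[2], shift[3])
    rows[[length(rows) + 1]] <- atom_row("A", i, "ALA", "CB",
                                         i * 3.8 + shift[1], 1.5 + shift[2],
                                         shift[3])
  }
  do.call(rbind, rows)
}

apply_rigid <- function(atoms, R, tvec) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + tvec[1]
  atoms$y <- xyz[, 2] + tvec[2]
  atoms$z <- xyz[, 3] + tvec[3]
  atoms
}
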