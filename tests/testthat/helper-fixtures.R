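# shared fixtures: generator duplexes are cheap, but cache the common ones
CRYSTAL_SEQ <- "GTAGGACCATC"   # the 11-mer duplex sequence used throughout
LONG_SEQ <- "GGGTAGTAGGACCATCGG"

fixture_env <- new.env(parent = emptyenv())

fixture_duplex <- function(form = "B", sequence = CRYSTAL_SEQ,
                           hybrid = "none") {
  key <- paste(form, sequence, hybrid, sep = "_")
  if (is.null(fixture_env[[key]])) {
    m <- build_fiber_duplex(sequence, fiber_spec(form), hybrid = hybrid)
    m <- assign_radii(m)
    fixture_env[[key]] <- pair_bases(m)
  }
  fixture_env[[key]]
}

fixture_geometry <- function(form = "B", sequence = CRYSTAL_SEQ) {
  key <- paste("geom", form, sequence, sep = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- duplex_geometry(fixture_duplex(form, sequence))
  }
  fixture_env[[key]]
}

# one residue's atoms from a model
model_residue <- function(model, chain, resno) {
  model$atoms[model$atoms$chain == chain & model$atoms$resno == resno, ,
              drop = FALSE]
}

# random rigid motion (proper rotation + translation), deterministic by seed
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- agraft:::rot_axis(ax, runif(1, 10, 170))
  list(R = R, t = rnorm(3, sd = 20))
}

transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- t(R %*% t(xyz)) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
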