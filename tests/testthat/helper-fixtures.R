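# Shared fixtures: all generated in code, nothing read from disk except
# the packaged ethanol force-field files.

ethanol_elements <- c("H", "H", "H", "H", "H", "C", "C", "O", "H")

# randomly perturbed ethanol-like configuration (well-separated atoms)
perturbed_ethanol <- function(sd = 0.05) {
  g <- ethanol_geometry()
  g$coords <- g$coords + matrix(stats::rnorm(27, sd = sd), 9, 3)
  g
}

# random "generic" geometry with a clash guard (broad pair-distance
# coverage; good design-matrix conditioning)
random_generic_geometry <- function(elements = ethanol_elements, box = 4,
                                    min_dist = 0.7) {
  n <- length(elements)
  repeat {
    x <- matrix(stats::runif(3 * n, 0, box), n, 3)
    if (min(stats::dist(x)) > min_dist)
      return(geometry(elements, x))
  }
}

empty_angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                           type = character(0), ka = numeric(0),
                           theta_e = numeric(0))
empty_dihedrals <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                              l = integer(0), type = character(0),
                              kd = numeric(0), n = integer(0),
                              delta = numeric(0))
empty_bonds <- data.frame(i = integer(0), j = integer(0),
                          type = character(0), style = character(0),
                          k = numeric(0), re = numeric(0), de = numeric(0))

# single-bond diatomic force field
diatomic_ff <- function(style = "morse", k = 1056.6764, re = 0.9609,
                        de = 110.66, elements = c("O", "H")) {
  forcefield(elements,
             data.frame(i = 1L, j = 2L, type = "A-B", style = style,
                        k = k, re = re, de = de),
             empty_angles, empty_dihedrals)
}

# memoized ethanol order-2 basis (used by several test files)
.basis_cache <- new.env(parent = emptyenv())
ethanol_basis2 <- function() {
  if (is.null(.basis_cache$b2))
    .basis_cache$b2 <- build_pip_basis(ethanol_symmetry(), 2)
  .basis_cache$b2
}
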