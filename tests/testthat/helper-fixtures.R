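# small fixtures shared across tests; everything is built in code

toy_tree <- function() read_newick("((A:1,B:1):1,C:2.5);")

star_newick <- function(n, depth = 1) {
  paste0("(", paste(sprintf("s%02d:%g", seq_len(n), depth),
                    collapse = ","), ");")
}

star_tree <- function(n, depth = 1) {
  suppressMessages(read_newick(star_newick(n, depth)))
}

named7 <- function(...) {
  v <- c(...)
  stats::setNames(rep(v, length.out = 7), TRAIT_NAMES)
}

zero_shift_spec <- function(sd = named7(0)) {
  trait_shift_spec(mean_shift = named7(0), shift_sd = sd)
}

# a small trait table with values far from zero (no flooring effects)
toy_trait_table <- function(n = 8, seed = 1, env = "cultivated") {
  set.seed(seed)
  m <- matrix(abs(stats::rnorm(n * 7, mean = 10, sd = 1)), n, 7,
              dimnames = list(sprintf("sp%03d", seq_len(n)), TRAIT_NAMES))
  trait_table(m, environment = env)
}

tip_values <- function(tt, trait) {
  stats::setNames(tt$traits[, trait], tt$species)
}
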