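# Shared designs and simulation specs used across the suite.

design_232 <- function(n = c(14, 16)) {
  rm_design(within = c(Location = 2, Texture = 3),
            between = c(Drink = 2), n = n)
}

design_2w_mixed <- function(a = 2, b = 2, n = 8) {
  w <- c(A = a); b2 <- c(B = b)
  rm_design(within = w, between = b2, n = n)
}

spec_232 <- function(n = c(14, 16), seed = 1, null = FALSE, ...) {
  eff <- if (null) list() else
    list(Location = c(-0.3, 0.3), Texture = c(-0.2, 0, 0.2),
         Drink = c(-0.25, 0.25))
  sim_spec(design_232(n), effects = eff,
           variance = c(sigma2 = 1, `Subject(Drink)` = 1,
                        `Subject(Drink):Location` = 0.5,
                        `Subject(Drink):Texture` = 0.4),
           seed = seed, ...)
}

# canonical string form of an EMS row, for symbolic identity checks
ems_keys <- function(ems, term) {
  sort(vapply(ems$rows[[term]], function(cm)
    paste0(paste(sort(cm$coef), collapse = "*"), "|", cm$symbol), ""))
}
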