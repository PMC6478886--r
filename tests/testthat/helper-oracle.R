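# Independent full-decomposition sums-of-squares oracle for balanced
# mixed-measures data, computed from cell / marginal means only (no shared
# code with the package's contrast-based fitting path).

# mean of y within each combination of `by` columns, returned per row
mean_by <- function(dat, by, y = "y") {
  if (!length(by)) return(rep(mean(dat[[y]]), nrow(dat)))
  key <- interaction(dat[by], drop = TRUE)
  stats::ave(dat[[y]], key)
}

# balanced fixed-term SS via inclusion-exclusion over sub-means
oracle_fixed_ss <- function(dat, term_factors, y = "y") {
  est <- rep(0, nrow(dat))
  k <- length(term_factors)
  for (j in 0:k) {
    sets <- if (j == 0) list(character()) else
      utils::combn(term_factors, j, simplify = FALSE)
    for (V in sets) {
      est <- est + (-1)^(k - j) * mean_by(dat, V, y)
    }
  }
  sum(est^2)
}

# full partition for the two-within + one-between layout
oracle_3way_mixed <- function(dat, subject = "Subject",
                              within = c("Location", "Texture"),
                              between = "Drink", y = "y") {
  w1 <- within[1L]; w2 <- within[2L]
  ss <- c(
    A  = oracle_fixed_ss(dat, w1, y),
    B  = oracle_fixed_ss(dat, w2, y),
    C  = oracle_fixed_ss(dat, between, y),
    AB = oracle_fixed_ss(dat, c(w1, w2), y),
    AC = oracle_fixed_ss(dat, c(w1, between), y),
    BC = oracle_fixed_ss(dat, c(w2, between), y),
    ABC = oracle_fixed_ss(dat, c(w1, w2, between), y))
  ysub <- mean_by(dat, subject, y)
  ygrp <- mean_by(dat, between, y)
  ss["S"] <- sum((ysub - ygrp)^2)
  ss["SA"] <- sum((mean_by(dat, c(subject, w1), y) -
                     mean_by(dat, c(between, w1), y) - ysub + ygrp)^2)
  ss["SB"] <- sum((mean_by(dat, c(subject, w2), y) -
                     mean_by(dat, c(between, w2), y) - ysub + ygrp)^2)
  ss["E"] <- sum((dat[[y]] - mean(dat[[y]]))^2) - sum(ss)
  lev <- c(length(unique(dat[[w1]])), length(unique(dat[[w2]])),
           length(unique(dat[[between]])))
  nsub <- length(unique(dat[[subject]]))
  df <- c(A = lev[1] - 1, B = lev[2] - 1, C = lev[3] - 1,
          AB = (lev[1] - 1) * (lev[2] - 1),
          AC = (lev[1] - 1) * (lev[3] - 1),
          BC = (lev[2] - 1) * (lev[3] - 1),
          ABC = prod(lev - 1),
          S = nsub - lev[3],
          SA = (nsub - lev[3]) * (lev[1] - 1),
          SB = (nsub - lev[3]) * (lev[2] - 1))
  df["E"] <- (nsub - lev[3]) * (lev[1] - 1) * (lev[2] - 1)
  ms <- ss / df[names(ss)]
  Fv <- c(A = ms[["A"]] / ms[["SA"]], B = ms[["B"]] / ms[["SB"]],
          C = ms[["C"]] / ms[["S"]], AB = ms[["AB"]] / ms[["E"]],
          AC = ms[["AC"]] / ms[["SA"]], BC = ms[["BC"]] / ms[["SB"]],
          ABC = ms[["ABC"]] / ms[["E"]])
  list(SS = ss, df = df, MS = ms, F = Fv)
}

# map oracle names to the package's effect labels for the 2x3x2 design
oracle_label_map <- c(A = "Location", B = "Texture", C = "Drink",
                      AB = "Location:Texture", AC = "Location:Drink",
                      BC = "Texture:Drink", ABC = "Location:Texture:Drink",
                      S = "Subject(Drink)", SA = "Subject(Drink):Location",
                      SB = "Subject(Drink):Texture", E = "Residual")
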