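# Independent brute-force planning oracle. Works from the raw segment
# table only, with its own enumeration, fraction, HI, dominance and
# tie-break logic; shares nothing with the package implementation except
# the option-id naming convention used to compare outcomes.
oraclePlan <- function(tab, denominator = "treatable", primary = "both",
                       s1w = c(30, 70), s2w = c(40, 80), cw = c(95, 130),
                       cap = 1700, himin = 1.2, eqtol = 2.0, ttol = 0.30,
                       target = 110) {
  tab$segment_id <- toupper(tab$segment_id)
  if (!"LB1+2" %in% tab$segment_id) {
    i1 <- tab$segment_id == "LB1"; i2 <- tab$segment_id == "LB2"
    tab <- rbind(tab[, c("segment_id", "tissue_ml", "air_ml")],
                 data.frame(segment_id = "LB1+2",
                            tissue_ml = tab$tissue_ml[i1] + tab$tissue_ml[i2],
                            air_ml = tab$air_ml[i1] + tab$air_ml[i2]))
  }
  tisv <- setNames(tab$tissue_ml, tab$segment_id)
  airv <- setNames(tab$air_ml, tab$segment_id)
  tarOf <- function(id) unname(100 * tisv[id] / airv[id])
  totOf <- function(id) unname(tisv[id] + airv[id])
  sideOf <- function(id) if (substr(id, 1, 1) == "L") "left" else "right"
  lower <- c(left = tarOf("LLL"), right = tarOf("RLL"))
  denomOf <- function(side) {
    ids <- if (side == "left") c("LB1", "LB2", "LB3")
           else c("RB1", "RB2", "RB3")
    v <- sum(vapply(ids, totOf, 0))
    if (denominator == "anatomical" && side == "left")
      v <- v + totOf("LB4") + totOf("LB5")
    v
  }
  s1of <- list(left = list("LB1", "LB2", "LB3", "LB1+2"),
               right = list("RB1", "RB2", "RB3"))
  s2of <- list(left = list("LB1", "LB2", "LB3", "LB1+2",
                           c("LB1", "LB3"), c("LB2", "LB3"),
                           c("LB1+2", "LB3")),
               right = list("RB1", "RB2", "RB3", c("RB1", "RB2"),
                            c("RB1", "RB3"), c("RB2", "RB3")))
  sides <- if (primary == "both") c("left", "right") else primary

  cand <- list()
  for (ps in sides) {
    ss <- if (ps == "left") "right" else "left"
    for (s1 in s1of[[ps]]) for (s2 in s2of[[ss]]) {
      treated <- c(s1, s2)
      s1v <- totOf(s1)
      s2v <- sum(vapply(s2, totOf, 0))
      f1 <- 100 * s1v / denomOf(ps)
      f2 <- 100 * s2v / denomOf(ss)
      his <- vapply(treated, function(id)
        lower[[sideOf(id)]] / tarOf(id), 0)
      ct <- 100 * sum(tisv[treated]) / sum(airv[treated])
      ok <- f1 >= s1w[1] && f1 <= s1w[2] && f2 >= s2w[1] && f2 <= s2w[2] &&
        f1 + f2 >= cw[1] && f1 + f2 <= cw[2] && s1v <= cap && s2v <= cap &&
        all(his >= himin)
      cand[[length(cand) + 1L]] <- list(
        id = paste0(ps, ":", s1, "|",
                    paste(sort(s2, method = "radix"), collapse = ",")),
        comb = f1 + f2, ctar = ct, ok = ok,
        treatedBase = unique(unlist(lapply(treated, function(id)
          if (id == "LB1+2") c("LB1", "LB2") else id))))
    }
  }
  feas <- Filter(function(x) x$ok, cand)
  if (!length(feas)) return(list(feasible = FALSE, id = NA_character_))

  uniqueLeast <- function(side) {
    ids <- if (side == "left") c("LB1", "LB2", "LB3")
           else c("RB1", "RB2", "RB3")
    t <- vapply(ids, tarOf, 0)
    mx <- max(t)
    if (sum(t == mx) == 1L && all(mx - t[t != mx] > eqtol))
      ids[which.max(t)] else NA_character_
  }
  least <- c(uniqueLeast("left"), uniqueLeast("right"))
  least <- least[!is.na(least)]
  if (length(least)) {
    keep <- Filter(function(x) !any(least %in% x$treatedBase), feas)
    if (length(keep)) feas <- keep
  }
  if (length(feas) == 1L)
    return(list(feasible = TRUE, id = feas[[1]]$id))
  ctars <- vapply(feas, function(x) x$ctar, 0)
  tie <- feas[ctars - min(ctars) <= ttol]
  dist <- vapply(tie, function(x) abs(x$comb - target), 0)
  ids <- vapply(tie, function(x) x$id, "")
  best <- order(dist, ids, method = "radix")[1L]
  list(feasible = TRUE, id = ids[best])
}
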