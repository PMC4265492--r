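#' Classify disease rank of a lobe's segments
#'
#' Segmental TARs within \code{tolerance} percentage points of each other
#' are considered equally diseased. A unique least-diseased segment exists
#' iff the largest TAR exceeds every other TAR by more than the tolerance;
#' symmetrically for the unique most-diseased segment. Segments at an end
#' of the range that is not uniquely resolved are labelled \code{"tied"};
#' the rest are \code{"intermediate"}.
#'
#' @param tars named numeric vector of segmental TARs (>= 2 segments).
#' @param tolerance equal-disease tolerance, TAR points (default 2.0).
#' @return data.frame: \code{segment_id}, \code{tar}, \code{rank} in
#'   \code{most|least|intermediate|tied}.
#' @examples
#' classifyDiseaseRank(c(LB1 = 9.0, LB2 = 10.5, LB3 = 13.0))
#' @export
classifyDiseaseRank <- function(tars, tolerance = 2.0) {
  if (length(tars) < 2L)
    stop("disease ranking needs at least two segments", call. = FALSE)
  if (is.null(names(tars)) || any(!nzchar(names(tars))))
    stop("'tars' must be named by segment id", call. = FALSE)
  mx <- max(tars); mn <- min(tars)
  leastUnique <- sum(tars > mx - .Machine$double.eps^0.5) == 1L &&
    all(mx - tars[tars != mx] > tolerance)
  mostUnique <- sum(tars < mn + .Machine$double.eps^0.5) == 1L &&
    all(tars[tars != mn] - mn > tolerance)
  rank <- rep("intermediate", length(tars))
  if (leastUnique) rank[which.max(tars)] <- "least"
  else rank[mx - tars <= tolerance] <- "tied"
  if (mostUnique) rank[which.min(tars)] <- "most"
  else rank[tars - mn <= tolerance] <- "tied"
  data.frame(segment_id = names(tars), tar = unname(tars), rank = rank,
             stringsAsFactors = FALSE)
}

# Unique least-diseased base segment of one upper lobe, or NA.
.uniqueLeast <- function(model, side, tolerance) {
  seg <- model@segments
  base <- seg[seg$side == side & seg$region == "upper" &
                seg$segment_id != .LEFT_MERGED, ]
  rk <- classifyDiseaseRank(setNames(base$tar, base$segment_id), tolerance)
  id <- rk$segment_id[rk$rank == "least"]
  if (length(id) == 1L) id else NA_character_
}

.treatsSegment <- function(options, segment_id) {
  vapply(seq_len(nrow(options)), function(i) {
    treated <- .expandBase(c(options$session1[i],
                             strsplit(options$session2[i], ",")[[1]]))
    segment_id %in% treated
  }, logical(1))
}

#' Select the preferred treatment plan
#'
#' Runs the full selection on a lung model: enumerate options, apply the
#' constraints, then (1) remove any option that treats a lobe's unique
#' least-diseased segment, unless every surviving option does; (2) if a
#' single option remains it is chosen; otherwise (3) take the options whose
#' combined TAR is within the similarity tolerance (0.30 TAR points) of the
#' minimum — the option with the lowest combined TAR treats the most
#' disease; (4) within that tie group prefer the combined fraction closest
#' to the 110% target; (5) break residual exact ties lexicographically by
#' option id. An empty survivor set yields a "no feasible plan" outcome,
#' not an error; the audit explains every exclusion.
#'
#' @param model a \linkS4class{LungModel}.
#' @param constraints a \linkS4class{PlanConstraints}.
#' @param primary_side \code{"both"}, \code{"left"} or \code{"right"}.
#' @return a \linkS4class{PlanSelection}.
#' @examples
#' m <- generateLungFixture(seed = 42)
#' sel <- selectPlan(m)
#' isFeasible(sel)
#' @export
selectPlan <- function(model, constraints = planConstraints(),
                       primary_side = "both") {
  stopifnot(is(model, "LungModel"), is(constraints, "PlanConstraints"))
  audit <- applyConstraints(enumerateOptions(model, primary_side),
                            constraints)
  audit$removed_least_diseased <- FALSE
  audit$tie_group <- FALSE
  audit$target_distance <- abs(audit$combined_fraction -
                                 constraints@combinedTarget)

  rank <- do.call(rbind, lapply(c("left", "right"), function(sd) {
    seg <- model@segments
    base <- seg[seg$side == sd & seg$region == "upper" &
                  seg$segment_id != .LEFT_MERGED, ]
    rk <- classifyDiseaseRank(setNames(base$tar, base$segment_id),
                              constraints@equalDiseaseTol)
    rk$side <- sd
    rk
  }))
  notes <- character()

  surv <- which(audit$pass)
  if (!length(surv)) {
    notes <- c(notes, "no option satisfies every constraint")
    return(new("PlanSelection", feasible = FALSE,
               chosen = audit[0, ], audit = audit, diseaseRank = rank,
               constraints = constraints, notes = notes))
  }

  # dominance: drop options treating a unique least-diseased segment,
  # unless all remaining options treat one
  leastIds <- na.omit(c(.uniqueLeast(model, "left",
                                     constraints@equalDiseaseTol),
                        .uniqueLeast(model, "right",
                                     constraints@equalDiseaseTol)))
  if (length(leastIds)) {
    treatsLeast <- Reduce(`|`, lapply(leastIds, function(id)
      .treatsSegment(audit[surv, , drop = FALSE], id)))
    if (any(!treatsLeast)) {
      audit$removed_least_diseased[surv[treatsLeast]] <- TRUE
      surv <- surv[!treatsLeast]
      notes <- c(notes, sprintf(
        "removed %d option(s) treating least-diseased segment(s) %s",
        sum(treatsLeast), paste(leastIds, collapse = ", ")))
    } else
      notes <- c(notes,
                 "all surviving options treat a least-diseased segment; none removed")
  }

  if (length(surv) > 1L) {
    minTar <- min(audit$combined_tar[surv])
    tie <- surv[audit$combined_tar[surv] - minTar <=
                  constraints@combinedTarTol]
    audit$tie_group[tie] <- TRUE
    if (length(tie) > 1L)
      notes <- c(notes, sprintf(
        "%d option(s) within %.2f TAR points of the minimum combined TAR %.3f%%; preferring combined fraction closest to %g%%",
        length(tie), constraints@combinedTarTol, minTar,
        constraints@combinedTarget))
    best <- tie[cOrder(audit$target_distance[tie],
                       audit$option_id[tie])][1L]
  } else {
    best <- surv
    audit$tie_group[best] <- TRUE
    notes <- c(notes, "single surviving option")
  }

  new("PlanSelection", feasible = TRUE,
      chosen = audit[best, , drop = FALSE], audit = audit,
      diseaseRank = rank, constraints = constraints, notes = notes)
}

#' Re-validate a selection against the raw volumes
#'
#' Recomputes every derived quantity of the chosen option from the lung
#' model and checks all constraints from scratch. Used by the plan
#' verification pass and by the test suite's feasibility invariant.
#'
#' @param selection a \linkS4class{PlanSelection}.
#' @param model the \linkS4class{LungModel} it was computed from.
#' @return TRUE invisibly; errors when a recomputed value disagrees with
#'   the audit or a constraint is violated.
#' @export
revalidatePlan <- function(selection, model) {
  stopifnot(is(selection, "PlanSelection"))
  if (!selection@feasible) return(invisible(TRUE))
  ch <- selection@chosen
  fresh <- applyConstraints(enumerateOptions(model, "both"),
                            selection@constraints)
  row <- fresh[fresh$option_id == ch$option_id, ]
  if (nrow(row) != 1L)
    stop("chosen option not reproducible from the model", call. = FALSE)
  num <- c("s1_volume_ml", "s2_volume_ml", "s1_fraction", "s2_fraction",
           "combined_fraction", "min_hi", "combined_tar")
  if (any(abs(unlist(row[num]) - unlist(ch[num])) > 1e-9))
    stop("audited values disagree with recomputation", call. = FALSE)
  if (!row$pass)
    stop("chosen option fails a constraint on re-check", call. = FALSE)
  invisible(TRUE)
}

#' @rdname PlanSelection-class
#' @export
setMethod("isFeasible", "PlanSelection", function(x) x@feasible)

#' @rdname PlanSelection-class
#' @export
setMethod("chosenOption", "PlanSelection", function(x) x@chosen)

#' @rdname PlanSelection-class
#' @export
setMethod("planAudit", "PlanSelection", function(x) x@audit)

#' @rdname PlanSelection-class
#' @export
setMethod("diseaseRank", "PlanSelection", function(x) x@diseaseRank)

setMethod("show", "PlanSelection", function(object) {
  if (object@feasible) {
    ch <- object@chosen
    cat("PlanSelection: feasible\n")
    cat(sprintf("  session 1 (%s lobe): %s  [%.0f ml, %.1f%% of lobe]\n",
                ch$primary_side, ch$session1, ch$s1_volume_ml,
                ch$s1_fraction))
    cat(sprintf("  session 2 (%s lobe): %s  [%.0f ml, %.1f%% of lobe]\n",
                .otherSide(ch$primary_side), ch$session2, ch$s2_volume_ml,
                ch$s2_fraction))
    cat(sprintf("  combined fraction %.1f%% (target %g%%), combined TAR %.3f%%\n",
                ch$combined_fraction, object@constraints@combinedTarget,
                ch$combined_tar))
  } else cat("PlanSelection: no feasible plan\n")
  cat("  options audited:", nrow(object@audit), "\n")
})
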