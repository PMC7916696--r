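#' Sequential order of band responses from Noda's sign rules
#'
#' Applies the standard sign rules to every cross-peak: with both the
#' synchronous and asynchronous intensities positive at (nu1, nu2), the band
#' at nu1 responds to the perturbation prior to the band at nu2; a negative
#' asynchronous intensity reverses that; and a negative synchronous intensity
#' reverses whichever of the two verdicts the asynchronous sign gave.  An
#' asynchronous intensity indistinguishable from zero means the two bands
#' respond in phase; a synchronous intensity indistinguishable from zero
#' leaves the pair indeterminate.
#'
#' A best-effort transitive closure over shared band coordinates is attempted
#' on the "first" relations; inferred relations are appended with rule
#' \code{"transitive closure"}.  Directed cycles (mutually inconsistent
#' verdicts) are reported in \code{cycles} and never auto-resolved: the rules
#' yield pairwise statements, not a guaranteed total order.
#'
#' @param peaks a peak data frame from [detectCrosspeaks()] (auto-peaks are
#'   ignored); all peaks must come from the same [CorrelationMaps-class].
#' @return an object of class \code{SequentialOrder}: a list with
#'   \code{relations} (data frame \code{nu1}, \code{nu2}, \code{verdict} in
#'   \{\code{nu1_first}, \code{nu2_first}, \code{in_phase},
#'   \code{indeterminate}\}, \code{rule}) and \code{cycles} (list of
#'   wavenumber vectors forming inconsistent loops).
#' @examples
#' sim <- generateSeries(syntheticSpec(list(
#'   bandSpec(1000, 10, onsetT = 270), bandSpec(1100, 10, onsetT = 310))))
#' maps <- correlate2d(sim$series)
#' applyNodaRules(detectCrosspeaks(maps))
#' @export
applyNodaRules <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  cps <- peaks[peaks$kind == "cross", , drop = FALSE]
  rel <- data.frame(
    nu1 = numeric(), nu2 = numeric(),
    verdict = character(), rule = character(), stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(cps))) {
    ss <- cps$sync_sign[r]
    as_ <- cps$async_sign[r]
    v <- if (ss == "~0") {
      c("indeterminate", "sync ~0: no interpretable correlation")
    } else if (as_ == "~0") {
      c("in_phase", "async ~0: perturbation affects both bands in phase")
    } else if (ss == "+" && as_ == "+") {
      c("nu1_first", "sync > 0, async > 0: nu1 responds prior to nu2")
    } else if (ss == "+" && as_ == "-") {
      c("nu2_first", "sync > 0, async < 0: nu2 responds prior to nu1")
    } else if (ss == "-" && as_ == "+") {
      c("nu2_first", "sync < 0, async > 0: rule reversed, nu2 responds prior to nu1")
    } else {
      c("nu1_first", "sync < 0, async < 0: rule reversed, nu1 responds prior to nu2")
    }
    rel <- rbind(rel, data.frame(
      nu1 = cps$nu1[r], nu2 = cps$nu2[r],
      verdict = v[1L], rule = v[2L], stringsAsFactors = FALSE
    ))
  }

  cycles <- list()
  if (nrow(rel)) {
    # directed graph on band coordinates: edge a -> b means a responds first
    firsts <- rel[rel$verdict %in% c("nu1_first", "nu2_first"), , drop = FALSE]
    if (nrow(firsts)) {
      from <- ifelse(firsts$verdict == "nu1_first", firsts$nu1, firsts$nu2)
      to <- ifelse(firsts$verdict == "nu1_first", firsts$nu2, firsts$nu1)
      nodes <- sort(unique(c(from, to)))
      nn <- length(nodes)
      reach <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
      reach[cbind(match(from, nodes), match(to, nodes))] <- TRUE
      for (m in seq_len(nn)) {          # Warshall reachability
        reach <- reach | (reach[, m] %o% reach[m, ])
      }
      mutual <- which(reach & t(reach), arr.ind = TRUE)
      mutual <- mutual[mutual[, 1L] < mutual[, 2L], , drop = FALSE]
      if (nrow(mutual)) {
        seen <- logical(nn)
        for (r in seq_len(nrow(mutual))) {
          i <- mutual[r, 1L]
          if (seen[i]) next
          comp <- sort(unique(c(i, which(reach[i, ] & reach[, i]))))
          seen[comp] <- TRUE
          cycles[[length(cycles) + 1L]] <- nodes[comp]
        }
      }
      # transitive closure: append inferred orderings not already stated
      stated <- paste(pmin(rel$nu1, rel$nu2), pmax(rel$nu1, rel$nu2))
      direct <- matrix(FALSE, nn, nn)
      direct[cbind(match(from, nodes), match(to, nodes))] <- TRUE
      inferred <- which(reach & !direct & !t(reach), arr.ind = TRUE)
      for (r in seq_len(nrow(inferred))) {
        a <- nodes[inferred[r, 1L]]; b <- nodes[inferred[r, 2L]]
        key <- paste(min(a, b), max(a, b))
        if (key %in% stated) next
        stated <- c(stated, key)
        rel <- rbind(rel, data.frame(
          nu1 = max(a, b), nu2 = min(a, b),
          verdict = if (max(a, b) == a) "nu1_first" else "nu2_first",
          rule = "transitive closure", stringsAsFactors = FALSE
        ))
      }
    }
  }
  structure(list(relations = rel, cycles = cycles), class = "SequentialOrder")
}

#' @export
print.SequentialOrder <- function(x, ...) {
  cat(sprintf("SequentialOrder: %d pairwise relation(s), %d cycle(s)\n",
              nrow(x$relations), length(x$cycles)))
  if (nrow(x$relations)) print(x$relations, row.names = FALSE)
  if (length(x$cycles)) {
    cat("inconsistent loops:\n")
    for (cy in x$cycles) cat(" ", paste(cy, collapse = " <-> "), "\n")
  }
  invisible(x)
}

#' Score an inferred sequential order against a known ground truth
#'
#' For every ground-truth band pair, looks for an inferred relation whose
#' coordinates match the two band centers within \code{tol} cm^-1 (in either
#' orientation; the closest match wins) and classifies it:
#' \code{"match"} when the verdict agrees with the true relation
#' (\code{before}/\code{after} against the first-responder verdicts,
#' \code{simultaneous} against \code{in_phase}), \code{"mismatch"} when it
#' disagrees or is indeterminate, \code{"undetected"} when no relation maps
#' onto the pair.  Pairs whose true relation is \code{"ambiguous"} are
#' excluded from scoring.
#'
#' @param order a \code{SequentialOrder} from [applyNodaRules()].
#' @param truth a ground-truth data frame from [generateSeries()].
#' @param tol coordinate matching tolerance in cm^-1 (default 10).
#' @return list with \code{report} (per-pair data frame: \code{center_a},
#'   \code{center_b}, \code{relation}, \code{outcome}) and \code{fraction}
#'   (matches / scored pairs; \code{NaN} when nothing was scored).
#' @export
recoverOrder <- function(order, truth, tol = 10) {
  stopifnot(inherits(order, "SequentialOrder"), is.data.frame(truth))
  truth <- truth[truth$relation != "ambiguous", , drop = FALSE]
  rel <- order$relations
  outcomes <- character(nrow(truth))
  for (r in seq_len(nrow(truth))) {
    a <- truth$center_a[r]; b <- truth$center_b[r]
    dFwd <- pmax(abs(rel$nu1 - a), abs(rel$nu2 - b))
    dRev <- pmax(abs(rel$nu1 - b), abs(rel$nu2 - a))
    d <- pmin(dFwd, dRev)
    hit <- which(d <= tol)
    if (!length(hit)) {
      outcomes[r] <- "undetected"
      next
    }
    best <- hit[which.min(d[hit])]
    v <- rel$verdict[best]
    aIsNu1 <- dFwd[best] <= dRev[best]
    expected <- switch(truth$relation[r],
      before = if (aIsNu1) "nu1_first" else "nu2_first",
      after = if (aIsNu1) "nu2_first" else "nu1_first",
      simultaneous = "in_phase"
    )
    outcomes[r] <- if (identical(v, expected)) "match" else "mismatch"
  }
  report <- cbind(truth, outcome = outcomes, stringsAsFactors = FALSE)
  scored <- sum(outcomes != "")
  list(
    report = report,
    fraction = if (nrow(truth)) sum(outcomes == "match") / nrow(truth) else NaN
  )
}

#' Vibrational band assignments for TEMPO-oxidized cellulose / bPEI sponges
#'
#' Static lookup of the mid-infrared band inventory of cellulose nano-sponges
#' built from TEMPO-oxidized, ultra-sonicated cellulose nano-fibers
#' cross-linked by branched polyethyleneimine.  Used only to label peaks in
#' reports; no automated chemical assignment is attempted.
#'
#' @return data frame with columns \code{center} (cm^-1) and
#'   \code{assignment}.
#' @export
bandAssignments <- function() {
  data.frame(
    center = c(899, 985, 1000, 1021, 1031, 1055, 1108, 1159, 1203,
               1311, 1370, 1428, 1583, 1596, 1635, 1654, 1730,
               2900, 3242, 3254, 3270, 3307, 3330, 3347, 3360, 3374),
    assignment = c(
      "C-O-C stretching of glycosidic bonds",
      "in-plane CH rocking",
      "in-plane CH rocking",
      "C-N stretching of terminal C-NH2 units (bPEI)",
      "C-OH stretching, primary alcohol",
      "C-OH stretching, secondary alcohol (internal standard)",
      "asymmetric C-O-C stretching",
      "C-C ring breathing",
      "C-OH / C-CH bending",
      "CH2 rocking, amorphous cellulose",
      "CH/CH2 bending",
      "CH/CH2 bending",
      "residual COO- deformation",
      "N-H deformation (bPEI)",
      "HOH bending of adsorbed water",
      "amide C=O stretching (-CONH-)",
      "free carboxylic C=O stretching",
      "CH/CH2 symmetric stretching",
      "interchain O(6)H..O(3') / O(3)H..O(6') hydrogen bonds",
      "interchain O(6)H..O(3') / O(3)H..O(6') hydrogen bonds",
      "intrachain O(2)H..O(6) hydrogen bonds",
      "N-H stretching",
      "O-H stretching",
      "N-H stretching of bonded amides (bPEI)",
      "intrachain O(3)H..O(5) hydrogen bonds",
      "intrachain O(3)H..O(5) hydrogen bonds"
    ),
    stringsAsFactors = FALSE
  )
}

nearestAssignment <- function(nu, tol = 12) {
  tab <- bandAssignments()
  vapply(nu, function(x) {
    i <- which.min(abs(tab$center - x))
    if (abs(tab$center[i] - x) <= tol) tab$assignment[i] else ""
  }, "")
}

#' Write peak tables, order reports and slices
#'
#' \code{writePeakTable} writes a peak data frame as CSV with an added
#' \code{assignment} column from [bandAssignments()].
#' \code{writeOrderReport} writes the relations as CSV and, alongside it, a
#' human-readable text report stating each ordering as "nu1 changes prior to
#' nu2". \code{writeSlice} writes a two-column CSV of an asynchronous slice.
#'
#' @param peaks a peak data frame.
#' @param order a \code{SequentialOrder}.
#' @param slice a slice data frame from [sliceAsync()].
#' @param path,csvPath,txtPath output paths.
#' @return the written path(s), invisibly.
#' @export
writePeakTable <- function(peaks, path) {
  out <- peaks
  out$assignment <- nearestAssignment(peaks$nu1)
  writeTableCSV(out, path)
}

#' @rdname writePeakTable
#' @export
writeOrderReport <- function(order, csvPath, txtPath = NULL) {
  stopifnot(inherits(order, "SequentialOrder"))
  writeTableCSV(order$relations, csvPath)
  if (!is.null(txtPath)) {
    lines <- c("Sequential order of band responses (Noda sign rules)",
               strrep("-", 52))
    rel <- order$relations
    for (r in seq_len(nrow(rel))) {
      lines <- c(lines, switch(rel$verdict[r],
        nu1_first = sprintf("%g cm-1 changes prior to %g cm-1  [%s]",
                            rel$nu1[r], rel$nu2[r], rel$rule[r]),
        nu2_first = sprintf("%g cm-1 changes prior to %g cm-1  [%s]",
                            rel$nu2[r], rel$nu1[r], rel$rule[r]),
        in_phase = sprintf("%g and %g cm-1 change in phase", rel$nu1[r], rel$nu2[r]),
        indeterminate = sprintf("%g vs %g cm-1: indeterminate", rel$nu1[r], rel$nu2[r])
      ))
    }
    if (length(order$cycles)) {
      lines <- c(lines, "", "Inconsistent loops (not resolved):")
      for (cy in order$cycles) {
        lines <- c(lines, paste(" ", paste(cy, collapse = " <-> ")))
      }
    }
    con <- file(txtPath, open = "wb")
    writeLines(lines, con)
    close(con)
  }
  invisible(c(csvPath, txtPath))
}

#' @rdname writePeakTable
#' @export
writeSlice <- function(slice, path) {
  out <- data.frame(nu1 = slice$nu1, async = slice$async)
  writeTableCSV(out, path)
}

# deterministic CSV writer (LF line endings, 17 significant digits)
writeTableCSV <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = TRUE, na = "",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
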