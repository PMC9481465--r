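type_index <- function(lattice, type_id) {
  if (is.character(type_id)) {
    idx <- match(type_id, lattice$types)
    if (is.na(idx)) stop("unknown type: ", type_id)
    idx
  } else as.integer(type_id)
}

type_mask <- function(lattice, idx) {
  ids <- which(lattice$cell_type == idx)
  (matrix(lattice$grid %in% ids, nrow(lattice$grid))) * 1L
}

#' Contiguity of one cell type's tissue
#'
#' Counts the connected components of the union of all sites of a type,
#' using the same connectivity order as the CPM copy neighbourhood so
#' that dynamics and scoring agree. A type is contiguous when its sites
#' form a single component.
#'
#' @param lattice A `cpm_lattice`.
#' @param type_id Type label (`"ES"`, `"TS"`, `"XEN"`) or index.
#' @param neighbourhood Connectivity order (1 = 4-connected,
#'   2 = 8-connected).
#' @return List with `component_count` and `contiguous`.
#' @export
type_contiguity <- function(lattice, type_id, neighbourhood = 2L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  idx <- type_index(lattice, type_id)
  mask <- type_mask(lattice, idx)
  if (!any(mask == 1L)) {
    stop("type ", lattice$types[idx], " is absent from the lattice")
  }
  lab <- cpp_label_components(mask, as.integer(neighbourhood))
  n <- max(lab)
  list(component_count = n, contiguous = n == 1L)
}

#' Pairwise contact lengths by type
#'
#' Boundary-link census between unlike cells, tallied by type pair over
#' `{ES, TS, XEN, Medium}`. Entry `("XEN", "Medium")` is the length of
#' aggregate surface held by XEN tissue; diagonal entries count links
#' between different cells of the same type.
#'
#' @inheritParams type_contiguity
#' @return Symmetric 4x4 numeric matrix with dimnames.
#' @export
contact_lengths <- function(lattice, neighbourhood = 2L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  m <- cpp_contact_lengths(lattice$grid, lattice$cell_type,
                           as.integer(neighbourhood))
  dimnames(m) <- list(c(lattice$types, "Medium"),
                      c(lattice$types, "Medium"))
  m
}

#' Fraction of the aggregate surface held by one type
#'
#' The aggregate-medium boundary is the set of cell-medium neighbour
#' links; a type's envelopment fraction is its share of those links. The
#' three fractions sum to 1, and a type forming a complete outer
#' monolayer scores 1.
#'
#' @inheritParams type_contiguity
#' @return Fraction in `[0, 1]`.
#' @export
envelopment_fraction <- function(lattice, type_id, neighbourhood = 2L) {
  idx <- type_index(lattice, type_id)
  m <- contact_lengths(lattice, neighbourhood)
  surface <- m[1:3, "Medium"]
  tot <- sum(surface)
  if (tot == 0) stop("empty aggregate: no cell-medium boundary")
  unname(surface[idx] / tot)
}

#' Is XEN tissue interposed between the ES and TS compartments?
#'
#' `TRUE` iff there is no direct ES-TS contact while both compartments
#' contact XEN — the arrangement where XEN separates the embryonic and
#' trophoblast compartments.
#'
#' @inheritParams type_contiguity
#' @return Logical flag.
#' @export
xen_interposition <- function(lattice, neighbourhood = 2L) {
  m <- contact_lengths(lattice, neighbourhood)
  present <- vapply(1:3, function(i) any(lattice$cell_type == i), logical(1))
  if (!all(present)) {
    stop("missing type(s): ",
         paste(lattice$types[!present], collapse = ", "))
  }
  m["ES", "TS"] == 0 && m["ES", "XEN"] > 0 && m["TS", "XEN"] > 0
}

#' The 16-class taxonomy of sorted configurations
#'
#' Configurations are scored by which cell type envelops the aggregate
#' (occupies at least the threshold share of the aggregate-medium
#' boundary) and whether each of the two remaining types is contiguous,
#' the same two features used to select well- versus mis-sorted
#' structures experimentally. The sorted label space enumerates to
#' exactly 16:
#' \itemize{
#'   \item XEN envelope (5): both inner compartments contiguous and in
#'     contact (`ETX-like`), contiguous but separated by XEN tissue
#'     (`env(XEN;ES|TS)`, the interposed arrangement), ES fragmented,
#'     TS fragmented, both fragmented;
#'   \item ES envelope (4): inner TS/XEN both contiguous, TS fragmented,
#'     XEN fragmented, both fragmented;
#'   \item TS envelope (4): likewise for inner ES/XEN;
#'   \item no envelope (3): the two non-dominant types (the boundary-
#'     dominant type is the one holding the largest surface share) both
#'     contiguous and in contact, both contiguous but separated by the
#'     dominant tissue, or exactly one fragmented.
#' }
#' A structure with no envelope and both non-dominant types fragmented
#' is `"unsorted"` (as is any unrecognized residue); a lattice missing a
#' type entirely is `"degenerate"`. Neither counts among the 16.
#'
#' `ETX-like` — XEN monolayer over adjacent contiguous ES and TS
#' compartments with an ES-TS interface — matches the criteria for
#' well-sorted synthetic embryos (one ES and one TS compartment under
#' an outside XEN layer).
#'
#' @return Data frame with columns `label_id`, `family`,
#'   `enveloping_type` (`NA` for the open classes), `interposition`
#'   (`TRUE` if the class implies XEN between ES and TS, `NA` if it
#'   depends on which type dominates), and `description`.
#' @export
configuration_taxonomy <- function() {
  rows <- list(
    list("ETX-like", "xen-enveloped", "XEN", FALSE,
         "XEN monolayer over adjacent contiguous ES and TS compartments"),
    list("env(XEN;ES|TS)", "xen-enveloped", "XEN", TRUE,
         "XEN envelope whose tissue also separates contiguous ES and TS"),
    list("env(XEN;ES-split)", "xen-enveloped", "XEN", FALSE,
         "XEN envelope, multiple ES compartments, one TS compartment"),
    list("env(XEN;TS-split)", "xen-enveloped", "XEN", FALSE,
         "XEN envelope, one ES compartment, multiple TS compartments"),
    list("env(XEN;both-split)", "xen-enveloped", "XEN", FALSE,
         "XEN envelope, multiple ES and multiple TS compartments"),
    list("env(ES;TS,XEN)", "es-enveloped", "ES", FALSE,
         "ES envelope over contiguous TS and XEN"),
    list("env(ES;TS-split)", "es-enveloped", "ES", FALSE,
         "ES envelope, multiple TS compartments, contiguous XEN"),
    list("env(ES;XEN-split)", "es-enveloped", "ES", FALSE,
         "ES envelope, contiguous TS, multiple XEN compartments"),
    list("env(ES;both-split)", "es-enveloped", "ES", FALSE,
         "ES envelope, multiple TS and multiple XEN compartments"),
    list("env(TS;ES,XEN)", "ts-enveloped", "TS", FALSE,
         "TS envelope over contiguous ES and XEN"),
    list("env(TS;ES-split)", "ts-enveloped", "TS", FALSE,
         "TS envelope, multiple ES compartments, contiguous XEN"),
    list("env(TS;XEN-split)", "ts-enveloped", "TS", FALSE,
         "TS envelope, contiguous ES, multiple XEN compartments"),
    list("env(TS;both-split)", "ts-enveloped", "TS", FALSE,
         "TS envelope, multiple ES and multiple XEN compartments"),
    list("open(adjacent)", "open", NA_character_, FALSE,
         "no envelope; the two non-dominant tissues touch each other"),
    list("open(separated)", "open", NA_character_, NA,
         "no envelope; the dominant tissue separates the other two"),
    list("open(one-split)", "open", NA_character_, FALSE,
         "no envelope; exactly one non-dominant tissue is fragmented")
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(label_id = r[[1]], family = r[[2]],
               enveloping_type = r[[3]], interposition = r[[4]],
               description = r[[5]])))
  stopifnot(!anyDuplicated(out$label_id))
  rownames(out) <- NULL
  out
}

#' Classify a lattice into the sorted-configuration taxonomy
#'
#' Scores a labelled lattice by per-type contiguity, envelopment
#' fractions and pairwise contact lengths, and maps the feature tuple to
#' one of the 16 sorted classes of [configuration_taxonomy()],
#' `"unsorted"` (no envelope and both non-dominant tissues fragmented),
#' or `"degenerate"` (a type absent). A type is enveloping when its
#' share of the aggregate surface reaches `envelopment_threshold`; the
#' default 0.9 tolerates a one-cell seam in an otherwise complete
#' monolayer on a ~25-cell aggregate.
#'
#' Deterministic, and invariant under lattice rotation, reflection and
#' within-type cell-id permutation.
#'
#' @inheritParams type_contiguity
#' @param envelopment_threshold Surface fraction defining envelopment.
#' @return Object of class `configuration_label`: list with `label_id`,
#'   `contiguous` (named logical), `enveloping_type` (or `NA`),
#'   `envelopment` (named fractions), `interposition` (XEN between ES
#'   and TS), and `contacts` (the 4x4 census).
#' @export
classify <- function(lattice, envelopment_threshold = 0.9,
                     neighbourhood = 2L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  types <- lattice$types
  present <- vapply(1:3, function(i) any(lattice$cell_type == i) &&
                      any(lattice$grid %in% which(lattice$cell_type == i)),
                    logical(1))
  feat <- list(label_id = NA_character_,
               contiguous = stats::setNames(rep(NA, 3), types),
               enveloping_type = NA_character_,
               envelopment = stats::setNames(rep(NA_real_, 3), types),
               interposition = NA, contacts = NULL)
  if (!all(present)) {
    feat$label_id <- "degenerate"
    return(structure(feat, class = "configuration_label"))
  }
  m <- contact_lengths(lattice, neighbourhood)
  surface <- m[1:3, "Medium"]
  env <- surface / sum(surface)
  contig <- vapply(1:3, function(i)
    type_contiguity(lattice, i, neighbourhood)$contiguous, logical(1))
  names(contig) <- types

  feat$contiguous <- contig
  feat$envelopment <- stats::setNames(as.numeric(env), types)
  feat$interposition <- m["ES", "TS"] == 0 && m["ES", "XEN"] > 0 &&
    m["TS", "XEN"] > 0
  feat$contacts <- m

  enveloping <- which(env >= envelopment_threshold)
  if (length(enveloping) == 1L) {
    feat$enveloping_type <- types[enveloping]
  }

  if (length(enveloping) == 1L) {
    a <- types[enveloping]
    bc <- sort(setdiff(types, a))       # inner pair in ES < TS < XEN order
    c1 <- contig[[bc[1]]]
    c2 <- contig[[bc[2]]]
    bc_contact <- m[bc[1], bc[2]]
    label <- if (c1 && c2) {
      if (a == "XEN") {
        if (bc_contact > 0) "ETX-like" else "env(XEN;ES|TS)"
      } else {
        sprintf("env(%s;%s,%s)", a, bc[1], bc[2])
      }
    } else if (!c1 && c2) {
      sprintf("env(%s;%s-split)", a, bc[1])
    } else if (c1 && !c2) {
      sprintf("env(%s;%s-split)", a, bc[2])
    } else {
      sprintf("env(%s;both-split)", a)
    }
  } else {
    # no envelope: score the two types that do not dominate the surface
    dom <- types[which.max(env)]        # which.max breaks ties by order
    nd <- sort(setdiff(types, dom))
    c1 <- contig[[nd[1]]]
    c2 <- contig[[nd[2]]]
    nd_contact <- m[nd[1], nd[2]]
    label <- if (c1 && c2) {
      if (nd_contact > 0) "open(adjacent)" else "open(separated)"
    } else if (xor(c1, c2)) {
      "open(one-split)"
    } else {
      "unsorted"
    }
  }
  feat$label_id <- label
  structure(feat, class = "configuration_label")
}

#' @export
print.configuration_label <- function(x, ...) {
  cat(sprintf("<configuration_label> %s\n", x$label_id))
  if (!is.null(x$contacts)) {
    cat(sprintf("  contiguous: %s | envelopment: %s | interposition: %s\n",
                paste(sprintf("%s=%s", names(x$contiguous), x$contiguous),
                      collapse = " "),
                paste(sprintf("%s=%.2f", names(x$envelopment),
                              x$envelopment), collapse = " "),
                x$interposition))
  }
  invisible(x)
}

#' Score every snapshot of a trajectory
#'
#' @param trajectory A `cpm_trajectory` from [run_simulation()].
#' @param envelopment_threshold Passed to [classify()].
#' @return Data frame with one row per recorded snapshot: `mcs`,
#'   `label_id`, contiguity flags, envelopment fractions,
#'   `interposition`.
#' @export
score_trajectory <- function(trajectory, envelopment_threshold = 0.9) {
  nb <- trajectory$params$config$lattice$neighbourhood
  rows <- lapply(seq_along(trajectory$snapshots), function(i) {
    cl <- classify(trajectory$snapshots[[i]], envelopment_threshold, nb)
    data.frame(mcs = trajectory$mcs[i], label_id = cl$label_id,
               es_contiguous = cl$contiguous[["ES"]],
               ts_contiguous = cl$contiguous[["TS"]],
               xen_contiguous = cl$contiguous[["XEN"]],
               env_ES = cl$envelopment[["ES"]],
               env_TS = cl$envelopment[["TS"]],
               env_XEN = cl$envelopment[["XEN"]],
               interposition = cl$interposition)
  })
  do.call(rbind, rows)
}

#' Summarize an ensemble of configuration labels
#'
#' Frequency table of final labels over an ensemble. For reporting,
#' labels observed at a frequency strictly below `group_threshold` are
#' merged into a single `"other (<threshold)"` entry; raw counts are
#' always retained. A label at exactly the threshold frequency is not
#' grouped.
#'
#' @param labels Character vector of label ids (one per run).
#' @param group_threshold Grouping frequency threshold.
#' @return Object of class `ensemble_summary`: list with `counts`
#'   (named, raw), `freq`, `grouped` (reporting view), `n_runs`,
#'   `group_threshold`.
#' @export
summarize_ensemble <- function(labels, group_threshold = 0.05) {
  stopifnot(length(labels) >= 1L)
  counts <- table(labels)
  counts <- counts[order(-counts, names(counts))]
  n <- length(labels)
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  small <- freq < group_threshold
  grouped <- c(freq[!small],
               if (any(small))
                 stats::setNames(sum(freq[small]),
                                 sprintf("other (<%g%%)",
                                         100 * group_threshold)))
  structure(list(counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 freq = freq, grouped = grouped, n_runs = n,
                 group_threshold = group_threshold),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d runs\n", x$n_runs))
  for (i in seq_along(x$grouped)) {
    cat(sprintf("  %-22s %5.1f%%\n", names(x$grouped)[i],
                100 * x$grouped[i]))
  }
  invisible(x)
}
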