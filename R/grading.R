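#' Ordinal perfusion grade levels
#'
#' Six gradable levels plus \code{UNGRADABLE}.  Each gradable level carries a
#' perfusion score (the midpoint-style weights used for averaging) and a
#' three-way category: \code{perfused} (fully perfused cells only),
#' \code{hypoperfused} (51–99\% perfused), \code{nonperfused} (0–50\%
#' perfused).
#'
#' @format Character vector of the seven level names, ordered from worst to
#'   best perfusion, \code{UNGRADABLE} last.
#' @export
grade_levels <- function() {
  c("P0", "P1_25", "P26_50", "P51_75", "P76_99", "P100", "UNGRADABLE")
}

.grade_scores <- c(P0 = 0, P1_25 = 0.125, P26_50 = 0.375,
                   P51_75 = 0.625, P76_99 = 0.875, P100 = 1)

.grade_categories <- c(P0 = "nonperfused", P1_25 = "nonperfused",
                       P26_50 = "nonperfused", P51_75 = "hypoperfused",
                       P76_99 = "hypoperfused", P100 = "perfused",
                       UNGRADABLE = "ungradable")

#' @export
#' @rdname grade_levels
category_levels <- function() c("perfused", "hypoperfused", "nonperfused", "ungradable")

#' Perfusion score of a grade
#'
#' Fixed map P100 -> 1, P76_99 -> 0.875, P51_75 -> 0.625, P26_50 -> 0.375,
#' P1_25 -> 0.125, P0 -> 0.  Ungradable cells carry no score.
#'
#' @param g Character vector of grade level names.
#' @return Numeric scores in [0, 1].
#' @export
grade_score <- function(g) {
  check_grades(g)
  if (any(g == "UNGRADABLE"))
    abort_no_score("UNGRADABLE cells have no perfusion score")
  unname(.grade_scores[g])
}

#' Category of a grade
#'
#' @param g Character vector of grade level names.
#' @return Character vector: perfused / hypoperfused / nonperfused /
#'   ungradable.
#' @export
grade_category <- function(g) {
  check_grades(g)
  unname(.grade_categories[g])
}

check_grades <- function(g) {
  if (!is.character(g) || !all(g %in% grade_levels()))
    abort_invalid("grades must be level names from grade_levels()")
  invisible(g)
}

#' One grader's per-cell grades for one image
#'
#' @param image_id,grader_id Identifiers.
#' @param grades data.frame with columns \code{ring}, \code{sector},
#'   \code{grade} (level names).
#' @param excluded Optional data.frame with columns \code{ring}, \code{sector}
#'   of cells not presented to the grader (e.g. off-image); disjoint from
#'   \code{grades}.
#' @param grid A \code{gridfa_grid}.
#' @return A \code{gridfa_session}.
#' @export
grading_session <- function(image_id, grader_id, grades,
                            excluded = NULL, grid = grid_spec()) {
  check_grid(grid)
  if (!is.data.frame(grades) ||
      !all(c("ring", "sector", "grade") %in% names(grades)))
    abort_invalid("`grades` needs columns ring, sector, grade")
  check_grades(grades$grade)
  gid <- cell_flat_id(grades$ring, grades$sector)   # validates addresses
  if (anyDuplicated(gid)) abort_invalid("duplicate cell in `grades`")
  if (any(grades$ring > grid$n_rings))
    abort_invalid("graded cell outside the grid")
  if (!is.null(excluded) && nrow(excluded)) {
    eid <- cell_flat_id(excluded$ring, excluded$sector)
    if (any(eid %in% gid))
      abort_invalid("a cell cannot be both graded and excluded")
  } else {
    excluded <- data.frame(ring = integer(0), sector = integer(0))
  }
  structure(
    list(image_id = as.character(image_id), grader_id = as.character(grader_id),
         grid = grid,
         grades = data.frame(ring = as.integer(grades$ring),
                             sector = as.integer(grades$sector),
                             grade = as.character(grades$grade)),
         excluded = data.frame(ring = as.integer(excluded$ring),
                               sector = as.integer(excluded$sector)),
         created = format(Sys.time(), tz = "UTC")),
    class = "gridfa_session"
  )
}

#' @export
print.gridfa_session <- function(x, ...) {
  cat(sprintf("Grading session: image '%s', grader '%s', %d graded / %d excluded cells\n",
              x$image_id, x$grader_id, nrow(x$grades), nrow(x$excluded)))
  invisible(x)
}

#' Aggregate a session over a named region
#'
#' Region perfusion is the mean perfusion score of graded, gradable cells in
#' the region; percent hypoperfusion is \code{100 * (1 - mean perfusion)}.
#' Ungradable cells appear in the category counts but never in the mean;
#' excluded cells contribute to neither.
#'
#' @param session A \code{gridfa_session}.
#' @param region Region name (see \code{\link{region_def}}).
#' @return List: \code{region}, \code{n_cells}, \code{n_excluded},
#'   \code{n_graded}, \code{n_ungradable}, \code{category_counts},
#'   \code{mean_perfusion}, \code{percent_hypoperfusion}, \code{gradable}
#'   (FALSE when no gradable cell exists; the means are then NA).
#' @export
region_summary <- function(session, region = "ENTIRE") {
  check_session(session)
  rd <- region_def(region, session$grid)
  g <- session$grades[session$grades$ring %in% rd$rings, , drop = FALSE]
  n_excl <- sum(session$excluded$ring %in% rd$rings)
  n_cells <- sum(ifelse(rd$rings == 0L, 1L, 8L * rd$rings))
  cats <- grade_category(g$grade)
  counts <- table(factor(cats, levels = category_levels()))
  gradable <- g$grade[g$grade != "UNGRADABLE"]
  mean_perf <- if (length(gradable)) mean(grade_score(gradable)) else NA_real_
  list(
    region = region,
    n_cells = n_cells,
    n_excluded = n_excl,
    n_graded = nrow(g),
    n_ungradable = sum(g$grade == "UNGRADABLE"),
    category_counts = counts,
    mean_perfusion = mean_perf,
    percent_hypoperfusion = 100 * (1 - mean_perf),
    gradable = length(gradable) > 0L
  )
}

check_session <- function(s) {
  if (!inherits(s, "gridfa_session"))
    abort_invalid("expected a gridfa_session")
  invisible(s)
}

#' Pair two graders' sessions of the same image cell-by-cell
#'
#' @param a,b Sessions of the same image by different graders.
#' @param drop_if_either_ungradable When TRUE, cells marked UNGRADABLE by
#'   either grader are removed (the count removed is reported).
#' @return List: \code{pairs} (data.frame image_id, ring, sector, grade1,
#'   grade2, category1, category2), \code{n_common}, \code{n_removed}.
#' @export
pair_sessions <- function(a, b, drop_if_either_ungradable = FALSE) {
  check_session(a); check_session(b)
  if (a$grader_id == b$grader_id)
    abort_incompatible_sessions("cannot pair a session with itself (same grader)")
  if (a$image_id != b$image_id)
    abort_incompatible_sessions("sessions grade different images")
  if (a$grid$n_rings != b$grid$n_rings || a$grid$r0 != b$grid$r0)
    abort_incompatible_sessions("sessions use different grids")
  ga <- a$grades; gb <- b$grades
  m <- merge(ga, gb, by = c("ring", "sector"), suffixes = c("1", "2"))
  n_common <- nrow(m)
  either_u <- m$grade1 == "UNGRADABLE" | m$grade2 == "UNGRADABLE"
  n_removed <- 0L
  if (drop_if_either_ungradable) {
    n_removed <- sum(either_u)
    m <- m[!either_u, , drop = FALSE]
  }
  m <- m[order(m$ring, m$sector), , drop = FALSE]
  pairs <- data.frame(
    image_id = rep(a$image_id, nrow(m)),
    ring = m$ring, sector = m$sector,
    grade1 = m$grade1, grade2 = m$grade2,
    category1 = grade_category(m$grade1),
    category2 = grade_category(m$grade2),
    row.names = NULL
  )
  list(pairs = pairs, n_common = n_common, n_removed = n_removed)
}

# Round half away from zero, the convention used for printed percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-grader category table over paired sessions
#'
#' Reproduces the layout of a two-grader category comparison: for each grader,
#' the number of cells graded and the percentage falling in each category
#' within the requested region, plus the per-category count difference
#' (grader 2 minus grader 1).  Display percentages are rounded half-up to
#' whole percents; exact counts and fractions are retained in the result.
#'
#' @param paired A single result of \code{\link{pair_sessions}} or a list of
#'   them (one per image).
#' @param region Region name.
#' @param grid A \code{gridfa_grid} (used for region ring membership).
#' @return List: \code{table} (data.frame grader x category percentages),
#'   \code{counts} (2 x 4 matrix of exact counts), \code{diff} (named vector,
#'   grader2 - grader1 per category), \code{n_cells}.
#' @export
tabulate_categories <- function(paired, region = "ENTIRE", grid = grid_spec()) {
  pairs <- rbind_pairs(paired)
  if (!nrow(pairs)) abort_invalid("no paired cells to tabulate")
  if ("ring" %in% names(pairs)) {
    rd <- region_def(region, grid)
    pairs <- pairs[pairs$ring %in% rd$rings, , drop = FALSE]
  } else if (region != "ENTIRE") {
    abort_invalid("paired table carries no cell addresses; only ENTIRE is available")
  }
  if (!nrow(pairs)) abort_invalid(sprintf("no paired cells in region %s", region))
  lv <- category_levels()
  c1 <- table(factor(pairs$category1, levels = lv))
  c2 <- table(factor(pairs$category2, levels = lv))
  counts <- rbind(grader1 = as.integer(c1), grader2 = as.integer(c2))
  colnames(counts) <- lv
  n <- nrow(pairs)
  tab <- data.frame(
    grader = c("grader1", "grader2"),
    cells_graded = c(n, n),
    round_half_up(100 * counts / n)
  )
  list(table = tab, counts = counts,
       diff = counts["grader2", ] - counts["grader1", ],
       n_cells = n)
}

rbind_pairs <- function(paired) {
  if (is.data.frame(paired)) return(paired)
  if (!is.null(paired$pairs)) return(paired$pairs)
  if (is.list(paired) && length(paired))
    return(do.call(rbind, lapply(paired, function(p)
      if (is.data.frame(p)) p else p$pairs)))
  abort_invalid("`paired` must be pair_sessions() output or a list of them")
}
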