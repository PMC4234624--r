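#' Configuration for a synthetic weekly cohort
#'
#' Describes a cohort of students who each week name the peers they worked
#' with. The defaults emulate a first-year cohort of ~160 students split
#' over 7 recitation/lab sections, with declining weekly survey
#' participation, roughly half of each week's links re-drawn from a
#' student's own past partners (link persistence), strong section homophily
#' and weaker gender homophily, and an end-of-course grade drawn
#' independently of everything else.
#'
#' @param n_students number of students in the cohort.
#' @param n_sections number of pre-assigned sections (balanced within 1).
#' @param gender_split probability of the category \code{"F"}.
#' @param grade_vocab character vector of grade categories, worst first
#'   (first category is the fail grade).
#' @param grade_weights sampling weights for the grades, same length.
#' @param n_weeks number of weekly networks to generate.
#' @param mean_out_degree expected number of namings per active student
#'   per week (Poisson).
#' @param persistence probability that an emitted link re-uses one of the
#'   student's previously used out-links rather than a new partner.
#' @param homophily_section,homophily_gender multiplicative preference
#'   weights (>= 1) for naming a partner in the same section / of the same
#'   gender when drawing a new partner.
#' @param participation per-week probability that a student is active
#'   (emits namings); length \code{n_weeks}. The default declines linearly,
#'   matching cohorts where survey fatigue thins out responses.
#' @param seed integer seed driving one reproducible random stream.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_students = 160,
                          n_sections = 7,
                          gender_split = 0.3,
                          grade_vocab = c("-3", "00", "02", "4", "7", "10", "12"),
                          grade_weights = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.15, 0.1),
                          n_weeks = 7,
                          mean_out_degree = 6,
                          persistence = 0.5,
                          homophily_section = 8,
                          homophily_gender = 2,
                          participation = seq(0.8, 0.5, length.out = n_weeks),
                          seed = 1L) {
  cfg <- list(n_students = as.integer(n_students),
              n_sections = as.integer(n_sections),
              gender_split = gender_split,
              grade_vocab = as.character(grade_vocab),
              grade_weights = as.numeric(grade_weights),
              n_weeks = as.integer(n_weeks),
              mean_out_degree = mean_out_degree,
              persistence = persistence,
              homophily_section = homophily_section,
              homophily_gender = homophily_gender,
              participation = as.numeric(participation),
              seed = as.integer(seed))
  probs <- c(cfg$gender_split, cfg$persistence, cfg$participation)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$homophily_section < 1 || cfg$homophily_gender < 1) {
    stop("homophily weights must be >= 1", call. = FALSE)
  }
  if (cfg$n_sections < 1L) stop("n_sections must be >= 1", call. = FALSE)
  if (cfg$n_students < 2L) stop("n_students must be >= 2", call. = FALSE)
  if (length(cfg$participation) != cfg$n_weeks) {
    stop("participation must have length n_weeks", call. = FALSE)
  }
  if (length(cfg$grade_weights) != length(cfg$grade_vocab) ||
      any(cfg$grade_weights < 0) || sum(cfg$grade_weights) <= 0) {
    stop("grade_weights must be non-negative, same length as grade_vocab",
         call. = FALSE)
  }
  if (cfg$mean_out_degree < 0) stop("mean_out_degree must be >= 0", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#' @param path YAML file whose keys match the [cohort_config()] arguments.
#' @return a \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown cohort config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, vals)
}

#' Generate node attributes for a synthetic cohort
#'
#' Sections are assigned in a shuffled round-robin, so section sizes are
#' balanced within one. Gender is i.i.d. Bernoulli(\code{gender_split});
#' grade is i.i.d. from the grade weights and independent of section and
#' gender by construction.
#'
#' @param cfg a [cohort_config()].
#' @return an \code{attribute_table} with ids \code{"s001"}, ...
#' @export
generate_attributes <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_students
  ids <- sprintf("s%03d", seq_len(n))
  section <- sample(rep_len(seq_len(cfg$n_sections), n))
  gender <- ifelse(stats::runif(n) < cfg$gender_split, "F", "M")
  grade <- sample(cfg$grade_vocab, n, replace = TRUE, prob = cfg$grade_weights)
  attribute_table(
    data.frame(id = ids, gender = gender,
               section = as.character(section), grade = grade,
               stringsAsFactors = FALSE),
    vocab = list(gender = c("F", "M"),
                 section = as.character(seq_len(cfg$n_sections)),
                 grade = cfg$grade_vocab))
}

#' Generate weekly directed networks for a synthetic cohort
#'
#' Each week every student is active with that week's participation
#' probability. An active student emits Poisson(\code{mean_out_degree})
#' namings; each naming is, with probability \code{persistence}, drawn
#' uniformly from the student's previously used out-links (when any exist),
#' and otherwise goes to a new partner drawn with probability proportional
#' to \code{homophily_section^[same section] * homophily_gender^[same
#' gender]}. Networks are simplified (no self-loops, no duplicate ordered
#' pairs). Students never leave the roster; declining participation alone
#' produces shrinking networks.
#'
#' @param cfg a [cohort_config()].
#' @param attrs attribute table from [generate_attributes()] (regenerated
#'   from \code{cfg} when omitted).
#' @return named list of weekly networks for weeks \code{1..n_weeks}.
#' @export
generate_weekly_networks <- function(cfg, attrs = generate_attributes(cfg)) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_students
  ids <- attrs$id
  section <- as.integer(attrs$section)
  gender <- as.integer(attrs$gender)
  # preference weight of i naming j, fixed over weeks
  log_ws <- log(cfg$homophily_section)
  log_wg <- log(cfg$homophily_gender)
  history <- vector("list", n)   # indices of partners ever named by i
  nets <- vector("list", cfg$n_weeks)
  for (t in seq_len(cfg$n_weeks)) {
    active <- which(stats::runif(n) < cfg$participation[t])
    src <- integer(0); dst <- integer(0)
    for (i in active) {
      k <- stats::rpois(1L, cfg$mean_out_degree)
      if (k == 0L) next
      prev <- history[[i]]
      reuse <- stats::runif(k) < cfg$persistence & length(prev) > 0L
      n_re <- sum(reuse); n_new <- k - n_re
      picks <- integer(0)
      if (n_re > 0L) picks <- prev[sample.int(length(prev), n_re, replace = TRUE)]
      if (n_new > 0L) {
        w <- exp(log_ws * (section == section[i]) + log_wg * (gender == gender[i]))
        w[i] <- 0
        picks <- c(picks, sample.int(n, min(n_new, n - 1L), prob = w))
      }
      picks <- unique(picks)
      history[[i]] <- union(prev, picks)
      src <- c(src, rep.int(i, length(picks)))
      dst <- c(dst, picks)
    }
    nets[[t]] <- simplify_network(
      weekly_network(data.frame(source = ids[src], target = ids[dst],
                                stringsAsFactors = FALSE),
                     week = t))
  }
  names(nets) <- as.character(seq_len(cfg$n_weeks))
  nets
}

#' Generate one full synthetic cohort (attributes + weekly networks)
#'
#' Replicate \code{k} reuses the configuration with seed \code{seed + k},
#' giving independent cohorts from one base seed.
#'
#' @param cfg a [cohort_config()].
#' @param replicate non-negative integer replicate offset added to the seed.
#' @return list with elements \code{attrs} and \code{networks}.
#' @export
generate_cohort <- function(cfg, replicate = 0L) {
  stopifnot(inherits(cfg, "cohort_config"))
  cfg$seed <- cfg$seed + as.integer(replicate)
  attrs <- generate_attributes(cfg)
  list(attrs = attrs, networks = generate_weekly_networks(cfg, attrs))
}
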