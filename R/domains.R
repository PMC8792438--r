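#' Group recordings into two-recording source domains plus a target
#'
#' Implements the two-partition multi-source grouping. In the
#' \code{cross_subject} scenario, recordings of different subjects within one
#' session are paired consecutively in \code{pairingOrder} (ascending subject
#' id by default), giving \code{N = length(recordings)/2} source domains — 7
#' for the standard 14 remaining subjects. In the \code{cross_session}
#' scenario, the two earlier sessions of one subject pool into a single
#' source domain (\code{N = 1}).
#'
#' @param recordings list of [FeatureTensor-class] source recordings.
#' @param target the target [FeatureTensor-class]; its labels are kept for
#'   evaluation only.
#' @param scenario \code{"cross_subject"} or \code{"cross_session"}.
#' @param pairingOrder optional integer permutation of the recordings used to
#'   pair them; default is the order given (callers should pass recordings in
#'   ascending subject-id order for reproducibility).
#' @param allowSingleton if TRUE an odd leftover recording forms a final
#'   one-member domain (duplicated member); default is a hard error.
#' @return A [DomainPartition-class].
#' @export
pairSources <- function(recordings, target,
                        scenario = c("cross_subject", "cross_session"),
                        pairingOrder = NULL, allowSingleton = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(all(vapply(recordings, is, logical(1), "FeatureTensor")),
            is(target, "FeatureTensor"))
  rid <- function(m) paste(m@subjectId, m@sessionId)
  if (rid(target) %in% vapply(recordings, rid, character(1)))
    msmraStop("msmra_overlap", "target recording %s also listed as a source",
              rid(target))
  if (!is.null(pairingOrder)) recordings <- recordings[pairingOrder]

  if (scenario == "cross_session") {
    if (length(recordings) != 2L)
      msmraStop("msmra_unpairable",
                "cross_session expects exactly the two earlier sessions, got %d recordings",
                length(recordings))
    sources <- list(new("SourceDomain", index = 1L, members = recordings))
  } else {
    n <- length(recordings)
    if (n %% 2L == 1L && !allowSingleton)
      msmraStop("msmra_unpairable",
                "odd number of source recordings; leftover recording is %s",
                rid(recordings[[n]]))
    nPair <- n %/% 2L
    sources <- lapply(seq_len(nPair), function(i)
      new("SourceDomain", index = i,
          members = recordings[(2L * i - 1L):(2L * i)]))
    if (n %% 2L == 1L) {
      sources[[nPair + 1L]] <- new("SourceDomain", index = nPair + 1L,
                                   members = recordings[n])
    }
  }
  new("DomainPartition", sources = sources, target = target,
      scenario = scenario)
}

#' Leave-one-out transfer splits over a subject x session grid
#'
#' \code{cross_subject}: one partition per (session, held-out subject), with
#' the remaining subjects of that session paired in ascending subject order.
#' \code{cross_session}: one partition per subject, with the first two
#' sessions pooled as the single source domain and the last session as
#' target (requires at least three sessions).
#'
#' @param grid list of [FeatureTensor-class] recordings covering a complete
#'   subject x session grid.
#' @param scenario \code{"cross_subject"} or \code{"cross_session"}.
#' @param allowSingleton passed to [pairSources()].
#' @return List of [DomainPartition-class] objects.
#' @export
leaveOneOutSplits <- function(grid,
                              scenario = c("cross_subject", "cross_session"),
                              allowSingleton = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(all(vapply(grid, is, logical(1), "FeatureTensor")))
  subj <- vapply(grid, function(g) g@subjectId, character(1))
  sess <- vapply(grid, function(g) g@sessionId, character(1))
  subjects <- sort(unique(subj))
  sessions <- sort(unique(sess))
  idx <- function(s, k) {
    w <- which(subj == s & sess == k)
    if (length(w) != 1L)
      msmraStop("msmra_incomplete_grid",
                "grid cell subject %s / session %s has %d recordings (expected 1)",
                s, k, length(w))
    w
  }
  ## validate completeness up front
  for (s in subjects) for (k in sessions) idx(s, k)

  splits <- list()
  if (scenario == "cross_subject") {
    for (k in sessions) {
      for (heldOut in subjects) {
        rest <- setdiff(subjects, heldOut)
        recs <- lapply(rest, function(s) grid[[idx(s, k)]])
        splits[[length(splits) + 1L]] <-
          pairSources(recs, grid[[idx(heldOut, k)]], "cross_subject",
                      allowSingleton = allowSingleton)
      }
    }
  } else {
    if (length(sessions) < 3L)
      msmraStop("msmra_incomplete_grid",
                "cross_session needs >= 3 sessions (two sources + target), got %d",
                length(sessions))
    src <- sessions[1:2]
    tgt <- sessions[length(sessions)]
    for (s in subjects) {
      recs <- lapply(src, function(k) grid[[idx(s, k)]])
      splits[[length(splits) + 1L]] <-
        pairSources(recs, grid[[idx(s, tgt)]], "cross_session")
    }
  }
  splits
}

#' Serializable description of a partition
#'
#' @param partition a [DomainPartition-class].
#' @return A list (JSON-ready) naming sources by subject/session id, the
#'   target id and the scenario.
#' @export
partitionManifest <- function(partition) {
  stopifnot(is(partition, "DomainPartition"))
  list(
    scenario = partition@scenario,
    n_domains = length(partition@sources),
    sources = lapply(partition@sources, function(s)
      lapply(s@members, function(m)
        list(subject_id = m@subjectId, session_id = m@sessionId,
             windows = nWindows(m)))),
    target = list(subject_id = partition@target@subjectId,
                  session_id = partition@target@sessionId,
                  windows = nWindows(partition@target))
  )
}
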