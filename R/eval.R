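#' Classify an annotated note from its gold mention labels
#'
#' Maps the gold labels of a note's mentions to a note-level class:
#' `tp_only`, `fp_only`, or `tn_only` when every mention shares one label,
#' and `conflicting` when the note carries both a true-positive and a
#' false-positive mention. A mixture of true-negative mentions with
#' exactly one other class resolves to that other class's "only" label,
#' with a warning — such notes do not occur in the reference annotation,
#' so the tie-break is a documented completion of the scheme.
#'
#' @param gold_classes Character vector of gold mention labels for one
#'   note (`true_positive`, `false_positive`, `true_negative`).
#' @return A single note-class string.
#' @export
classify_note <- function(gold_classes) {
  if (length(gold_classes) == 0) {
    stop("note has no gold mentions", call. = FALSE)
  }
  bad <- setdiff(unique(gold_classes),
                 c("true_positive", "false_positive", "true_negative"))
  if (length(bad)) {
    stop("unknown gold class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  has_tp <- "true_positive" %in% gold_classes
  has_fp <- "false_positive" %in% gold_classes
  has_tn <- "true_negative" %in% gold_classes
  if (has_tp && has_fp) {
    return("conflicting")
  }
  if (has_tn && (has_tp || has_fp)) {
    other <- if (has_tp) "tp_only" else "fp_only"
    warning("note mixes true-negative with ", other,
            " mentions; resolved to ", other, call. = FALSE)
    return(other)
  }
  if (has_tp) "tp_only" else if (has_fp) "fp_only" else "tn_only"
}

#' Tally an annotated note set
#'
#' Computes the note-class tally of a gold-annotated corpus: per-class
#' note counts (which partition the note set), the total number of
#' phrase occurrences, and mention-level precision
#' `TP / (TP + FP)` over all gold mentions. The tally is invariant to
#' note and mention ordering.
#'
#' @param gold A data frame of gold mention labels with columns `note_id`
#'   and `gold_class`.
#' @param notes A data frame (or character vector) of the annotated note
#'   set; every note must have at least one gold mention.
#' @return A list of class `sbdh_tally_report`: `occurrence_total`,
#'   `notes_tp_only`, `notes_fp_only`, `notes_tn_only`,
#'   `notes_conflicting`, `mention_precision`.
#' @export
tally_annotations <- function(gold, notes) {
  note_ids <- if (is.character(notes)) notes else notes$note_id
  missing <- setdiff(note_ids, gold$note_id)
  if (length(missing)) {
    stop("note(s) without gold annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  gold <- gold[gold$note_id %in% note_ids, ]
  classes <- vapply(
    split(gold$gold_class, gold$note_id),
    classify_note, character(1)
  )
  n_tp_m <- sum(gold$gold_class == "true_positive")
  n_fp_m <- sum(gold$gold_class == "false_positive")
  structure(
    list(
      occurrence_total = nrow(gold),
      notes_tp_only = sum(classes == "tp_only"),
      notes_fp_only = sum(classes == "fp_only"),
      notes_tn_only = sum(classes == "tn_only"),
      notes_conflicting = sum(classes == "conflicting"),
      mention_precision = if (n_tp_m + n_fp_m > 0) {
        n_tp_m / (n_tp_m + n_fp_m)
      } else {
        NA_real_
      }
    ),
    class = "sbdh_tally_report"
  )
}

# Map a predicted context class to its gold-label group.
context_to_gold <- function(context_class) {
  unname(c(
    affirmative = "true_positive",
    smartphrase_affirmative = "true_positive",
    negated = "false_positive",
    other_referent = "false_positive",
    smartphrase_negative = "true_negative"
  )[context_class])
}

#' Evaluate the rule-based miner against gold mention labels
#'
#' Matches predicted mention spans to gold mentions by exact offsets
#' (`note_id`, `start`, `end`). Matched spans whose predicted context
#' disagrees with the gold label count as context misclassifications,
#' not missed matches; gold mentions with no predicted span at all count
#' against span recall.
#'
#' @param predicted Classified mention spans (see [mine_notes()]).
#' @param gold Gold mention labels with columns `note_id`, `start`,
#'   `end`, `gold_class`.
#' @return A list: `confusion` (gold class x predicted class table over
#'   matched spans), `span_recall`, `context_accuracy`,
#'   `mention_precision` (precision of predicted-affirmative mentions
#'   against gold), `n_missed`, `n_spurious`.
#' @export
evaluate_miner <- function(predicted, gold) {
  key <- function(x) paste(x$note_id, x$start, x$end)
  pk <- key(predicted)
  if (anyDuplicated(pk)) {
    stop("duplicate predicted span(s): ",
         paste(unique(pk[duplicated(pk)]), collapse = "; "), call. = FALSE)
  }
  gk <- key(gold)
  m <- match(gk, pk)
  matched <- !is.na(m)
  pred_group <- context_to_gold(predicted$context_class[m[matched]])
  gold_cls <- gold$gold_class[matched]
  confusion <- table(
    gold = factor(gold_cls, levels = c("true_positive", "false_positive",
                                       "true_negative")),
    predicted = factor(pred_group,
                       levels = c("true_positive", "false_positive",
                                  "true_negative"))
  )
  pred_tp <- sum(pred_group == "true_positive")
  correct_tp <- sum(pred_group == "true_positive" &
                      gold_cls == "true_positive")
  list(
    confusion = confusion,
    span_recall = if (nrow(gold) > 0) sum(matched) / nrow(gold) else NA_real_,
    context_accuracy = if (sum(matched) > 0) {
      sum(pred_group == gold_cls) / sum(matched)
    } else {
      NA_real_
    },
    mention_precision = if (pred_tp > 0) correct_tp / pred_tp else NA_real_,
    n_missed = sum(!matched),
    n_spurious = sum(!pk %in% gk)
  )
}
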