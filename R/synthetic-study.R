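#' Define a synthetic multi-subject study
#'
#' Bundles every generator parameter plus the planted effect into a single
#' specification object. The defaults describe the validation world used
#' throughout the test suite: 20 subjects with two 15-minute sessions each,
#' 60 gray-matter parcels, a 3-parcel seed ROI, and a drowsy-minus-alert
#' connectivity increase of 0.2 Fisher-z units planted on parcels 11-45.
#'
#' @param n_subjects number of subjects (default 20).
#' @param sessions_per_subject sessions per subject (default 2).
#' @param duration_s session length in seconds (default 900).
#' @param tr_s BOLD repetition time (default 2.1 s, so a 63-s staging epoch
#'   spans exactly 30 volumes).
#' @param n_parcels number of BOLD parcels (default 60).
#' @param seed_parcels indices averaged into the seed ROI (default `1:3`).
#' @param effect_support indices of parcels carrying the planted state
#'   effect (default `11:45`, i.e. a widespread increase covering most of
#'   the gray matter, emulating the global drowsy-state coupling pattern).
#' @param delta_z planted drowsy-minus-alert shift in Fisher-z units
#'   (default 0.2).
#' @param r_baseline alert-state parcel-to-parcel correlation level
#'   (default 0.3).
#' @param transition_rate latent per-second state-switch probability
#'   (default 1/450: mean dwell of 7.5 min, consistent with the length of
#'   same-state vigilance runs seen in resting EEG-fMRI).
#' @param eeg_snr EEG band SNR (default 4).
#' @param eeg_sfreq EEG sampling rate (default 250 Hz).
#' @param dropout_frac respiratory dropout fraction (default 0.05).
#' @param mean_ibi_s mean inter-beat interval (default 1.0 s).
#' @param n_tissue named integer vector: number of synthetic white-matter,
#'   deep-CSF, and fourth-ventricle nuisance series.
#' @param rng_seed master RNG seed; every session derives its own child
#'   seeds from it, so the whole study is reproducible bit-for-bit.
#' @return an object of class `vigi_study_spec`.
#' @export
study_spec <- function(n_subjects = 20, sessions_per_subject = 2,
                       duration_s = 900, tr_s = 2.1, n_parcels = 60,
                       seed_parcels = 1:3, effect_support = 11:45,
                       delta_z = 0.2, r_baseline = 0.3,
                       transition_rate = 1 / 450, eeg_snr = 4,
                       eeg_sfreq = 250, dropout_frac = 0.05,
                       mean_ibi_s = 1.0,
                       n_tissue = c(wm = 8, csf = 8, fv = 4),
                       rng_seed = 20260101) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  assert_scalar_number(duration_s, "duration_s", lower = 60)
  assert_scalar_number(tr_s, "tr_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(dropout_frac, "dropout_frac", 0, 0.5,
                       strict_upper = TRUE)
  assert_scalar_number(transition_rate, "transition_rate", 0, 1,
                       strict_upper = TRUE)
  assert_scalar_number(eeg_snr, "eeg_snr", 0, strict_lower = TRUE)
  if (is.null(names(n_tissue)) && length(n_tissue) == 3) {
    names(n_tissue) <- c("wm", "csf", "fv")
  }
  if (any(effect_support < 1 | effect_support > n_parcels)) {
    vf_stop("effect_support must index parcels", "vigifc_parameter_error")
  }
  if (length(intersect(seed_parcels, effect_support)) > 0) {
    vf_stop("effect_support cannot include seed parcels",
            "vigifc_parameter_error")
  }
  effect_spec <- numeric(n_parcels)
  effect_spec[effect_support] <- delta_z
  structure(
    list(n_subjects = n_subjects,
         sessions_per_subject = sessions_per_subject,
         duration_s = duration_s, tr_s = tr_s, n_parcels = n_parcels,
         seed_parcels = seed_parcels, effect_support = effect_support,
         delta_z = delta_z, effect_spec = effect_spec,
         r_baseline = r_baseline, transition_rate = transition_rate,
         eeg_snr = eeg_snr, eeg_sfreq = eeg_sfreq,
         dropout_frac = dropout_frac, mean_ibi_s = mean_ibi_s,
         n_tissue = n_tissue, rng_seed = as.integer(rng_seed)),
    class = "vigi_study_spec"
  )
}

#' Enumerate the (subject, session) pairs of a study
#' @param spec a `vigi_study_spec`.
#' @return data.frame with columns `subject`, `session`.
#' @export
study_sessions <- function(spec) {
  stopifnot(inherits(spec, "vigi_study_spec"))
  expand.grid(session = seq_len(spec$sessions_per_subject),
              subject = seq_len(spec$n_subjects))[, c("subject", "session")]
}

#' Materialize one session of a synthetic study
#'
#' Generates the latent trajectory, EEG, BOLD, nuisance tissue series, and
#' peripheral waveforms for a single (subject, session) pair. Child RNG
#' seeds are derived deterministically from the study seed, so sessions can
#' be generated independently and in any order.
#'
#' @param spec a `vigi_study_spec`.
#' @param subject,session 1-based indices.
#' @return a session record: list with `subject_id`, `session_id`,
#'   `latent`, `eeg`, `bold`, `tissue` (list of wm/csf/fv matrices),
#'   `physio` (resp/pulse/pupil) and `tr_s`.
#' @export
generate_session <- function(spec, subject, session) {
  stopifnot(inherits(spec, "vigi_study_spec"))
  base <- child_seed(spec$rng_seed, subject * 101L + session)
  latent <- generate_latent(spec$duration_s, spec$transition_rate,
                            seed = child_seed(base, 1L))
  eeg <- generate_eeg(latent, sfreq = spec$eeg_sfreq, snr = spec$eeg_snr,
                      seed = child_seed(base, 2L))
  bold <- generate_bold(latent, spec$n_parcels, spec$tr_s, spec$effect_spec,
                        seed = child_seed(base, 3L),
                        r_baseline = spec$r_baseline,
                        seed_parcels = spec$seed_parcels)
  physio <- generate_physio(latent, dropout_frac = spec$dropout_frac,
                            mean_ibi_s = spec$mean_ibi_s,
                            seed = child_seed(base, 4L))
  g <- attr(bold, "global_factor")
  n_vol <- ncol(bold)
  tissue <- withr_seed(child_seed(base, 5L), {
    lapply(spec$n_tissue, function(k) {
      m <- 0.25 * matrix(g, k, n_vol, byrow = TRUE) +
        matrix(stats::rnorm(k * n_vol), k, n_vol)
      rownames(m) <- sprintf("t%02d", seq_len(k))
      m
    })
  })
  list(subject_id = subject, session_id = session, latent = latent,
       eeg = eeg, bold = bold, tissue = tissue, physio = physio,
       tr_s = spec$tr_s)
}

#' Materialize a whole study in memory
#'
#' Convenience wrapper for small studies; large studies should be streamed
#' one session at a time with [generate_session()] (a default-sized session
#' holds ~1.4M EEG samples).
#'
#' @param spec a `vigi_study_spec`.
#' @return list of session records, in `study_sessions()` order.
#' @export
simulate_study <- function(spec) {
  idx <- study_sessions(spec)
  lapply(seq_len(nrow(idx)), function(i) {
    generate_session(spec, idx$subject[i], idx$session[i])
  })
}

#' Ground-truth signed map implied by a study's planted effect
#' @param spec a `vigi_study_spec`.
#' @return integer vector of length `n_parcels` in \{-1, 0, +1\}.
#' @export
truth_signed_map <- function(spec) {
  sign(spec$effect_spec)
}

# ---------------------------------------------------------------------------
# Disk representation: one directory per session, all plain text (TSV/JSON).

write_waveform_tsv <- function(w, path) {
  n <- length(w$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / w$sfreq, value = w$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s\tvalue", con)
  writeLines(sprintf("%.6f\t%s", df$time_s,
                     ifelse(is.na(df$value), "NaN",
                            formatC(df$value, digits = 8, format = "g"))),
             con)
}

read_waveform_tsv <- function(path) {
  df <- utils::read.delim(path, na.strings = c("NaN", "NA"))
  dt <- diff(df$time_s[1:2])
  list(values = df$value, sfreq = round(1 / dt))
}

#' Write a session record to a directory of delimited-text files
#'
#' Layout: `eeg.tsv` (channels as columns), `bold.tsv` (parcels as
#' columns), `tissue_{wm,csf,fv}.tsv`, `resp.tsv` / `pulse.tsv` /
#' `pupil.tsv` (`time_s`, `value`; missing values written as `NaN`), and a
#' `ground_truth.json` sidecar with the per-second latent states, the
#' planted effect, and the seeds.
#'
#' @param rec a session record from [generate_session()].
#' @param dir output directory (created if needed).
#' @param spec the `vigi_study_spec` (recorded in the sidecar).
#' @return `dir`, invisibly.
#' @export
write_session <- function(rec, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eeg <- t(unclass(rec$eeg))
  utils::write.table(eeg, file.path(dir, "eeg.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(t(unclass(rec$bold)), file.path(dir, "bold.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (tis in names(rec$tissue)) {
    utils::write.table(t(rec$tissue[[tis]]),
                       file.path(dir, sprintf("tissue_%s.tsv", tis)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_waveform_tsv(rec$physio$resp, file.path(dir, "resp.tsv"))
  write_waveform_tsv(rec$physio$pulse, file.path(dir, "pulse.tsv"))
  write_waveform_tsv(rec$physio$pupil, file.path(dir, "pupil.tsv"))
  gt <- list(
    subject_id = rec$subject_id, session_id = rec$session_id,
    tr_s = rec$tr_s,
    eeg_sfreq = attr(rec$eeg, "sfreq"),
    montage = as.list(attr(rec$eeg, "montage")),
    latent_states = rec$latent$states,
    effect_spec = if (!is.null(spec)) spec$effect_spec else
      attr(rec$bold, "effect_spec"),
    seed_parcels = attr(rec$bold, "seed_parcels"),
    study_seed = if (!is.null(spec)) spec$rng_seed else NA
  )
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#' @param dir session directory.
#' @return a session record (same shape as [generate_session()] output).
#' @export
read_session <- function(dir) {
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  eeg <- t(as.matrix(utils::read.delim(file.path(dir, "eeg.tsv"))))
  montage <- unlist(gt$montage)
  rownames(eeg) <- names(montage)
  eeg <- structure(eeg, sfreq = gt$eeg_sfreq, montage = montage,
                   class = c("vigi_eeg", class(eeg)))
  bold <- t(as.matrix(utils::read.delim(file.path(dir, "bold.tsv"))))
  bold <- structure(bold, tr_s = gt$tr_s, effect_spec = gt$effect_spec,
                    seed_parcels = gt$seed_parcels,
                    class = c("vigi_bold", class(bold)))
  tissue <- list()
  for (tis in c("wm", "csf", "fv")) {
    f <- file.path(dir, sprintf("tissue_%s.tsv", tis))
    if (file.exists(f)) tissue[[tis]] <- t(as.matrix(utils::read.delim(f)))
  }
  latent <- structure(
    list(states = gt$latent_states, transition_rate = NA,
         duration_s = length(gt$latent_states)),
    class = "vigi_latent")
  list(subject_id = gt$subject_id, session_id = gt$session_id,
       latent = latent, eeg = eeg, bold = bold, tissue = tissue,
       physio = list(resp = read_waveform_tsv(file.path(dir, "resp.tsv")),
                     pulse = read_waveform_tsv(file.path(dir, "pulse.tsv")),
                     pupil = read_waveform_tsv(file.path(dir, "pupil.tsv"))),
       tr_s = gt$tr_s)
}
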