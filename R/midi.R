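# Minimal Standard MIDI File (SMF) layer: type 0/1, note on/off, tempo map.
# Timing is resolved to seconds at read time using the file's tempo events;
# controllers, pitch bend and sysex payloads are skipped.

# ---- byte-level helpers -----------------------------------------------------

.u32 <- function(raw4) sum(as.integer(raw4) * c(16777216, 65536, 256, 1))
.u16 <- function(raw2) sum(as.integer(raw2) * c(256, 1))

# Variable-length quantity starting at position i; returns value and the
# position just past it.
.read_vlq <- function(bytes, i) {
  val <- 0
  repeat {
    b <- as.integer(bytes[i]); i <- i + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = i)
}

.encode_vlq <- function(x) {
  x <- as.integer(x)
  out <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    out <- c(as.raw(bitwOr(x %% 128L, 128L)), out)
    x <- x %/% 128L
  }
  out
}

.be <- function(x, width) {
  x <- as.integer(x)
  as.raw(rev((x %/% 256^(0:(width - 1))) %% 256))
}

# ---- reading ----------------------------------------------------------------

#' Read note messages from a Standard MIDI File
#'
#' Parses an SMF (format 0 or 1), resolves ticks to seconds with the file's
#' tempo map (default 120 BPM when no tempo event is present), and pairs
#' note-on with note-off messages per channel and pitch. A note-on left open
#' at the end of its track is closed at the track's end with a warning.
#'
#' @param path Path to a `.mid` file.
#' @return Data frame with columns `pitch`, `onset`, `duration`, `velocity`
#'   (times in seconds), sorted by onset then pitch. Zero rows for a file
#'   with no notes.
#' @seealso [write_midi()], [group_chords()]
#' @export
read_midi <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd")
    stop("not a Standard MIDI File (missing MThd header)")
  if (.u32(bytes[5:8]) != 6) stop("malformed MThd chunk")
  format <- .u16(bytes[9:10])
  if (!format %in% c(0L, 1L)) stop("only SMF format 0 and 1 are supported")
  ntrks <- .u16(bytes[11:12])
  division <- .u16(bytes[13:14])
  if (division >= 32768L) stop("SMPTE time division is not supported")
  if (division == 0L) stop("invalid time division")

  pos <- 15L
  tempo_ticks <- 0; tempo_vals <- 500000  # default 120 BPM at tick 0
  notes <- list()
  for (trk in seq_len(ntrks)) {
    if (pos + 7L > length(bytes) + 1L) stop("truncated file: missing track")
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk")
      stop("malformed file: expected MTrk chunk")
    len <- .u32(bytes[(pos + 4L):(pos + 7L)])
    i <- pos + 8L
    end <- i + len
    tick <- 0
    status <- NULL
    open <- list()  # key "ch.pitch" -> list of (tick, velocity), FIFO
    while (i < end) {
      v <- .read_vlq(bytes, i); tick <- tick + v$value; i <- v$pos
      b <- as.integer(bytes[i])
      if (b >= 128L) { status <- b; i <- i + 1L }
      if (is.null(status)) stop("malformed track: data byte without status")
      hi <- status %/% 16L
      if (status == 255L) {                       # meta event
        type <- as.integer(bytes[i]); i <- i + 1L
        v <- .read_vlq(bytes, i); i <- v$pos
        if (type == 81L && v$value == 3L) {
          tempo_ticks <- c(tempo_ticks, tick)
          tempo_vals <- c(tempo_vals,
                          .u32(c(as.raw(0), bytes[i:(i + 2L)])))
        }
        i <- i + v$value
        status <- NULL                             # meta cancels running status
      } else if (status %in% c(240L, 247L)) {      # sysex
        v <- .read_vlq(bytes, i); i <- v$pos + v$value
        status <- NULL
      } else if (hi %in% c(8L, 9L)) {              # note off / note on
        pitch <- as.integer(bytes[i]); vel <- as.integer(bytes[i + 1L])
        i <- i + 2L
        ch <- status %% 16L
        key <- paste0(ch, ".", pitch)
        if (hi == 9L && vel > 0L) {
          open[[key]] <- c(open[[key]], list(list(tick = tick, vel = vel)))
        } else {
          q <- open[[key]]
          if (length(q) > 0L) {
            on <- q[[1]]
            open[[key]] <- q[-1]
            dur <- tick - on$tick
            if (dur <= 0) dur <- 1   # degenerate zero-length: one tick
            notes[[length(notes) + 1L]] <-
              c(pitch, on$tick, dur, on$vel)
          }  # stray note-off: ignored
        }
      } else if (hi %in% c(10L, 11L, 14L)) {
        i <- i + 2L
      } else if (hi %in% c(12L, 13L)) {
        i <- i + 1L
      } else stop(sprintf("unsupported status byte 0x%X", status))
    }
    hanging <- sum(lengths(open) > 0)
    if (hanging > 0L) {
      warning(sprintf(
        "%d note-on message(s) without note-off; closed at track end",
        sum(vapply(open, length, integer(1)))))
      for (key in names(open)) {
        for (on in open[[key]]) {
          pitch <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]][2])
          dur <- max(tick - on$tick, 1)
          notes[[length(notes) + 1L]] <- c(pitch, on$tick, dur, on$vel)
        }
      }
    }
    pos <- end
  }

  if (length(notes) == 0L)
    return(data.frame(pitch = integer(0), onset = numeric(0),
                      duration = numeric(0), velocity = integer(0)))

  mat <- do.call(rbind, notes)
  ord <- order(tempo_ticks)
  tmap <- list(ticks = tempo_ticks[ord], tempo = tempo_vals[ord])
  onset <- .ticks_to_seconds(mat[, 2], tmap, division)
  offset <- .ticks_to_seconds(mat[, 2] + mat[, 3], tmap, division)
  out <- data.frame(pitch = as.integer(mat[, 1]), onset = onset,
                    duration = offset - onset,
                    velocity = as.integer(mat[, 4]))
  out <- out[order(out$onset, out$pitch), ]
  rownames(out) <- NULL
  out
}

# Piecewise-linear tick -> seconds conversion given a tempo map
# (tempo in microseconds per quarter note, division in ticks per quarter).
.ticks_to_seconds <- function(ticks, tmap, division) {
  bt <- tmap$ticks; tp <- tmap$tempo
  # cumulative seconds at each tempo-change boundary
  csec <- c(0, cumsum(diff(bt) * tp[-length(tp)] / division / 1e6))
  seg <- findInterval(ticks, bt)
  seg[seg < 1L] <- 1L
  csec[seg] + (ticks - bt[seg]) * tp[seg] / division / 1e6
}

# ---- writing ----------------------------------------------------------------

#' Write a melody to a Standard MIDI File
#'
#' Emits a format-0 SMF with a single track: one tempo event, then paired
#' note-on/note-off messages for every pitch of every event. Reading the file
#' back with [read_midi()] and [group_chords()] reproduces the melody's pitch
#' sets and onsets up to tick quantization (about 1 ms at the defaults).
#'
#' @param m A [melody()]; an empty melody yields a valid file with no notes.
#' @param path Output path.
#' @param division Ticks per quarter note (default 480).
#' @param tempo Microseconds per quarter note (default 500000, i.e. 120 BPM).
#' @return The path, invisibly.
#' @export
write_midi <- function(m, path, division = 480L, tempo = 500000L) {
  sec_to_tick <- function(s) as.integer(round(s * 1e6 / tempo * division))
  ons <- NULL
  if (n_events(m) > 0L) {
    per <- lapply(seq_len(n_events(m)), function(i) {
      e <- m$events[i, ]
      p <- e$pitches[[1]]
      rbind(
        data.frame(tick = sec_to_tick(e$onset), on = 1L, pitch = p,
                   vel = e$velocity),
        data.frame(tick = sec_to_tick(e$onset + e$duration), on = 0L,
                   pitch = p, vel = 0L)
      )
    })
    ons <- do.call(rbind, per)
    ons <- ons[order(ons$tick, ons$on), ]   # note-offs first at equal ticks
  }

  body <- c(as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)), .be(tempo, 3))
  last <- 0L
  if (!is.null(ons)) for (i in seq_len(nrow(ons))) {
    delta <- ons$tick[i] - last
    last <- ons$tick[i]
    status <- if (ons$on[i] == 1L) 0x90 else 0x80
    body <- c(body, .encode_vlq(delta),
              as.raw(c(status, ons$pitch[i], ons$vel[i])))
  }
  body <- c(body, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))

  header <- c(charToRaw("MThd"), .be(6, 4), .be(0, 2), .be(1, 2),
              .be(division, 2))
  track <- c(charToRaw("MTrk"), .be(length(body), 4), body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, track), con)
  invisible(path)
}

#' Read a melody straight from a MIDI file
#'
#' Convenience composition of [read_midi()] and [group_chords()].
#'
#' @inheritParams read_midi
#' @inheritParams group_chords
#' @return A [melody()].
#' @export
read_melody_midi <- function(path, window = 0.05,
                             participant_id = NA_character_) {
  group_chords(read_midi(path), window = window,
               participant_id = participant_id)
}
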