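#' Muscle labelling scheme for the proximal leg
#'
#' The 18 individually segmented muscles of the proximal leg, with label ids
#' 1-18 assigned in the conventional reading order (quadriceps, adductors,
#' hamstrings, then the remaining thigh and gluteal muscles). Label 0 is
#' background everywhere in the package.
#'
#' @param n_muscles number of muscles to include (1-18); smaller schemes keep
#'   the first \code{n_muscles} entries and are used by down-scaled phantoms.
#' @return data frame with columns \code{id}, \code{abbrev}, \code{name}.
#' @export
#' @examples
#' muscle_scheme(6)
muscle_scheme <- function(n_muscles = 18) {
  stopifnot(n_muscles >= 1, n_muscles <= 18)
  abbrev <- c("RF", "VL", "VM", "VI", "PC", "AB", "AL", "AM", "BFL",
              "BFB", "ST", "SM", "SR", "TFL", "GC", "Gma", "Gme", "Gmi")
  name <- c("Rectus femoris", "Vastus lateralis", "Vastus medialis",
            "Vastus intermedius", "Pectineus", "Adductor brevis",
            "Adductor longus", "Adductor magnus",
            "Biceps femoris caput longus", "Biceps femoris caput brevis",
            "Semitendinosus", "Semimembranosus", "Sartorius",
            "Tensor fascia lata", "Gracilis", "Gluteus maximus",
            "Gluteus medius", "Gluteus minimus")
  data.frame(id = seq_len(n_muscles), abbrev = abbrev[seq_len(n_muscles)],
             name = name[seq_len(n_muscles)], stringsAsFactors = FALSE)
}

scheme_ids <- function(scheme) scheme$id
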