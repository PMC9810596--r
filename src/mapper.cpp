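#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Exhaustive alignment of short reads to a circular genome.
//
// Every circular offset on both strands is scanned; candidate loci are
// ranked by mismatch count. A read is UNIQUE iff exactly one locus attains
// the minimal mismatch count and that minimum is <= max_mismatches;
// equal-mismatch ties always yield MULTI. five_prime_pos is the 0-based
// genomic coordinate of the read's 5' base (on the minus strand, the
// highest-coordinate aligned base).

static char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".scan_reads")]]
DataFrame scan_reads(std::string genome, CharacterVector reads,
                     int max_mismatches) {
  const int L = (int) genome.size();
  std::string doubled = genome + genome;
  const int n = reads.size();

  IntegerVector out_pos(n), out_mm(n);
  CharacterVector out_strand(n), out_status(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int w = (int) fwd.size();
    std::string rev(w, 'N');
    for (int j = 0; j < w; ++j) rev[w - 1 - j] = comp(fwd[j]);

    int best_mm = max_mismatches + 1, n_best = 0;
    int best_o = -1; bool best_plus = true;

    for (int s = 0; s < 2; ++s) {
      const std::string &r = (s == 0) ? fwd : rev;
      for (int o = 0; o < L; ++o) {
        int mm = 0;
        for (int j = 0; j < w; ++j) {
          if (doubled[o + j] != r[j]) {
            if (++mm > max_mismatches) break;
          }
        }
        if (mm <= max_mismatches) {
          if (mm < best_mm) {
            best_mm = mm; n_best = 1; best_o = o; best_plus = (s == 0);
          } else if (mm == best_mm) {
            ++n_best;
          }
        }
      }
    }

    if (n_best == 0) {
      out_pos[i] = NA_INTEGER; out_mm[i] = NA_INTEGER;
      out_strand[i] = NA_STRING; out_status[i] = "UNMAPPED";
    } else if (n_best > 1) {
      out_pos[i] = NA_INTEGER; out_mm[i] = best_mm;
      out_strand[i] = NA_STRING; out_status[i] = "MULTI";
    } else {
      out_pos[i] = best_plus ? best_o : (best_o + w - 1) % L;
      out_mm[i] = best_mm;
      out_strand[i] = best_plus ? "+" : "-";
      out_status[i] = "UNIQUE";
    }
  }

  return DataFrame::create(_["five_prime_pos"] = out_pos,
                           _["strand"] = out_strand,
                           _["n_mismatches"] = out_mm,
                           _["status"] = out_status,
                           _["stringsAsFactors"] = false);
}
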