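#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// nucleotide bitmasks: A=1 C=2 G=4 T=8; IUPAC codes are unions.
static inline int base_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'R': return 1 | 4;  case 'Y': return 2 | 8;
    case 'S': return 2 | 4;  case 'W': return 1 | 8;
    case 'K': return 4 | 8;  case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
  }
}

static inline bool is_acgt(char c) {
  return c=='A' || c=='C' || c=='G' || c=='T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// Count characters in each string with ASCII code <= max_code
// (used for tallying low-quality bases in Phred+33 strings).
// [[Rcpp::export]]
IntegerVector count_char_le(CharacterVector x, int max_code) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(x[i]);
    int cnt = 0;
    for (; *s; ++s) if ((int)(unsigned char)(*s) <= max_code) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// Count occurrences of one character per string (e.g. 'N').
// [[Rcpp::export]]
IntegerVector count_char_eq(CharacterVector x, char target) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(x[i]);
    int cnt = 0;
    for (; *s; ++s) if (*s == target) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// Ungapped local adapter scan: TRUE if any adapter aligns to the sequence
// on some diagonal with a contiguous window of length >= min_len containing
// <= max_mm mismatches.  Checking windows of exactly min_len suffices: any
// longer qualifying alignment contains a qualifying min_len window.
// [[Rcpp::export]]
LogicalVector adapter_scan(CharacterVector seqs, CharacterVector adapters,
                           int min_len, int max_mm) {
  R_xlen_t n = seqs.size(), na = adapters.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    int ls = (int)std::strlen(s);
    bool hit = false;
    for (R_xlen_t a = 0; a < na && !hit; ++a) {
      const char *ad = CHAR(adapters[a]);
      int la = (int)std::strlen(ad);
      if (la < min_len || ls < min_len) continue;
      // diagonal offset d: adapter position j aligns to seq position j + d
      for (int d = -(la - min_len); d <= ls - min_len && !hit; ++d) {
        int j0 = d < 0 ? -d : 0;                    // first adapter pos on diagonal
        int j1 = (ls - d < la) ? ls - d : la;       // one past last adapter pos
        int span = j1 - j0;
        if (span < min_len) continue;
        // sliding window of exactly min_len along the diagonal
        int mm = 0;
        for (int j = j0; j < j0 + min_len; ++j)
          if (!(base_mask(ad[j]) & base_mask(s[j + d]) &&
                is_acgt(s[j + d]))) ++mm;
        if (mm <= max_mm) { hit = true; break; }
        for (int j = j0 + min_len; j < j1; ++j) {
          if (!(base_mask(ad[j]) & base_mask(s[j + d]) && is_acgt(s[j + d]))) ++mm;
          if (!(base_mask(ad[j - min_len]) & base_mask(s[j - min_len + d]) &&
                is_acgt(s[j - min_len + d]))) --mm;
          if (mm <= max_mm) { hit = true; break; }
        }
      }
    }
    out[i] = hit;
  }
  return out;
}

// Mismatches between `pattern` and the substring of each sequence starting
// at 1-based position `start`.  IUPAC codes in the pattern match their set;
// a read base must be a concrete A/C/G/T inside that set (N counts as a
// mismatch).  Sequences too short get NA.
// [[Rcpp::export]]
IntegerVector mismatch_at(CharacterVector seqs, std::string pattern, int start) {
  R_xlen_t n = seqs.size();
  int lp = (int)pattern.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    int ls = (int)std::strlen(s);
    if (start - 1 + lp > ls) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    const char *p0 = s + start - 1;
    for (int j = 0; j < lp; ++j) {
      char b = p0[j];
      if (!(is_acgt(b) && (base_mask(pattern[j]) & base_mask(b)))) ++mm;
    }
    out[i] = mm;
  }
  return out;
}

// TRUE if the pattern occurs anywhere in the sequence with <= max_mm
// mismatches (ungapped, pattern fully contained).
// [[Rcpp::export]]
LogicalVector contains_pattern(CharacterVector seqs, std::string pattern,
                               int max_mm) {
  R_xlen_t n = seqs.size();
  int lp = (int)pattern.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    int ls = (int)std::strlen(s);
    bool hit = false;
    for (int off = 0; off + lp <= ls && !hit; ++off) {
      int mm = 0;
      for (int j = 0; j < lp; ++j) {
        char b = s[off + j];
        if (!(is_acgt(b) && (base_mask(pattern[j]) & base_mask(b)))) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) hit = true;
    }
    out[i] = hit;
  }
  return out;
}

// Overlap-merge read pairs.  s1 is the terminus-oriented read, s2 the mate
// already reverse-complemented into the same orientation, so a suffix of s1
// overlaps a prefix of s2.  Among overlap sizes o in [min_overlap,
// min(l1,l2)] with identity >= min_identity, the offset maximizing the
// matched-base count (ties: the larger overlap) is chosen.  Disagreeing
// positions take the base with the higher quality; equal qualities give 'N'.
// Returns NA for pairs with no qualifying overlap.
// [[Rcpp::export]]
CharacterVector merge_pairs_cpp(CharacterVector s1, CharacterVector s2,
                                CharacterVector q1, CharacterVector q2,
                                int min_overlap, double min_identity) {
  R_xlen_t n = s1.size();
  CharacterVector out(n);
  std::string merged;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(s1[i]);  const char *b = CHAR(s2[i]);
    const char *qa = CHAR(q1[i]); const char *qb = CHAR(q2[i]);
    int la = (int)std::strlen(a), lb = (int)std::strlen(b);
    int lim = la < lb ? la : lb;
    int best_o = -1, best_match = -1;
    for (int o = min_overlap; o <= lim; ++o) {
      int match = 0;
      const char *pa = a + la - o;
      for (int j = 0; j < o; ++j) if (pa[j] == b[j] && is_acgt(pa[j])) ++match;
      if ((double)match / o >= min_identity &&
          (match > best_match || (match == best_match && o > best_o))) {
        best_match = match; best_o = o;
      }
    }
    if (best_o < 0) { out[i] = NA_STRING; continue; }
    merged.assign(a, la - best_o);
    const char *pa = a + la - best_o;
    const char *pqa = qa + la - best_o;
    for (int j = 0; j < best_o; ++j) {
      if (pa[j] == b[j]) merged.push_back(pa[j]);
      else if (pa[j] == 'N') merged.push_back(b[j]);
      else if (b[j] == 'N') merged.push_back(pa[j]);
      else if (pqa[j] > qb[j]) merged.push_back(pa[j]);
      else if (pqa[j] < qb[j]) merged.push_back(b[j]);
      else merged.push_back('N');
    }
    merged.append(b + best_o);
    out[i] = merged;
  }
  return out;
}

// Enumerate all k-mers of both strands of each read, skipping windows with
// non-ACGT characters.  Returns the k-mer strings and the 1-based read
// index each instance came from.
// [[Rcpp::export]]
List enum_kmers(CharacterVector seqs, int k) {
  std::vector<std::string> kmers;
  std::vector<int> reads;
  R_xlen_t n = seqs.size();
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(seqs[i]);
    int ls = (int)std::strlen(s);
    if (ls < k) continue;
    rc.resize(ls);
    for (int j = 0; j < ls; ++j) rc[ls - 1 - j] = comp_base(s[j]);
    // positions of nearest non-ACGT at or after each index (forward strand)
    for (int strand = 0; strand < 2; ++strand) {
      const char *t = strand == 0 ? s : rc.c_str();
      int bad = -1;  // last index with non-ACGT seen so far
      for (int j = 0; j < ls; ++j) {
        if (!is_acgt(t[j])) bad = j;
        if (j >= k - 1 && bad <= j - k) {
          kmers.emplace_back(t + j - k + 1, (size_t)k);
          reads.push_back((int)i + 1);
        }
      }
    }
  }
  return List::create(_["kmer"] = wrap(kmers), _["read"] = wrap(reads));
}

// Apply substitutions to sequences: for entry j, set position pos[j]
// (1-based) of string idx[j] (1-based) to base[j].  Returns a copy.
// [[Rcpp::export]]
CharacterVector apply_substitutions(CharacterVector seqs, IntegerVector idx,
                                    IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  R_xlen_t m = idx.size();
  for (R_xlen_t j = 0; j < m; ++j) {
    std::string s = as<std::string>(out[idx[j] - 1]);
    int p = pos[j] - 1;
    if (p >= 0 && p < (int)s.size()) {
      s[p] = CHAR(base[j])[0];
      out[idx[j] - 1] = s;
    }
  }
  return out;
}
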