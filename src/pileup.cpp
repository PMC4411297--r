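#include <Rcpp.h>
#include <cctype>
#include <cstdlib>
using namespace Rcpp;

// Decode the read-base column of one samtools mpileup text record into
// strand-split A/C/G/T call counts.
//
// Symbols: '.' and ',' are reference calls on the forward/reverse strand;
// upper/lower-case letters are variant calls on the forward/reverse strand;
// '^' (with its mapping-quality byte) and '$' delimit read segments and carry
// no call; '+N<seq>'/'-N<seq>' indel strings follow the anchoring call and
// consume no quality byte; '*'/'#', '>' and '<' occupy a read slot (one
// quality byte) but contribute no call. Calls below `min_base_quality`
// (Phred+33 qualities) are dropped.
//
// Returns an 8-column count matrix (A,C,G,T forward; A,C,G,T reverse).
// [[Rcpp::export(name = ".decode_pileup_calls")]]
List decode_pileup_calls(CharacterVector bases, CharacterVector quals,
                         CharacterVector ref, IntegerVector depth,
                         int min_base_quality) {
  int n = bases.size();
  IntegerMatrix counts(n, 8);
  IntegerVector bad_line = IntegerVector::create(0);
  std::string bad_reason;

  for (int i = 0; i < n; ++i) {
    const char *b = CHAR(STRING_ELT(bases, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    int nq = LENGTH(STRING_ELT(quals, i));
    char rb = toupper(CHAR(STRING_ELT(ref, i))[0]);
    int ref_col;
    switch (rb) {
      case 'A': ref_col = 0; break;
      case 'C': ref_col = 1; break;
      case 'G': ref_col = 2; break;
      case 'T': ref_col = 3; break;
      default:  ref_col = -1;  // e.g. N: reference calls are uncountable
    }
    int qi = 0;   // index into quality string (one byte per read slot)
    const char *p = b;
    bool bad = false;
    while (*p && !bad) {
      char c = *p;
      if (c == '^') {            // read start: '^' + mapping quality byte
        if (!*(p + 1)) { bad = true; bad_reason = "dangling '^'"; break; }
        p += 2;
        continue;
      }
      if (c == '$') { ++p; continue; }
      if (c == '+' || c == '-') {        // indel string: sign, length, bases
        ++p;
        if (!isdigit((unsigned char)*p)) { bad = true; bad_reason = "malformed indel"; break; }
        long len = 0;
        while (isdigit((unsigned char)*p)) { len = len * 10 + (*p - '0'); ++p; }
        for (long k = 0; k < len; ++k) {
          if (!*p) { bad = true; bad_reason = "truncated indel"; break; }
          ++p;
        }
        continue;
      }
      // every remaining symbol occupies one read slot / quality byte
      if (qi >= nq) { bad = true; bad_reason = "more read slots than quality bytes"; break; }
      int qual = (int)(unsigned char)q[qi] - 33;
      ++qi;
      ++p;
      if (c == '*' || c == '#' || c == '>' || c == '<') continue;
      if (qual < min_base_quality) continue;
      int col = -1;
      switch (c) {
        case '.': col = (ref_col >= 0) ? ref_col : -1; break;
        case ',': col = (ref_col >= 0) ? ref_col + 4 : -1; break;
        case 'A': col = 0; break;
        case 'C': col = 1; break;
        case 'G': col = 2; break;
        case 'T': col = 3; break;
        case 'a': col = 4; break;
        case 'c': col = 5; break;
        case 'g': col = 6; break;
        case 't': col = 7; break;
        case 'N': case 'n': col = -1; break;
        default:
          bad = true; bad_reason = "unrecognized symbol";
      }
      if (col >= 0) counts(i, col) += 1;
    }
    if (!bad && qi != nq) { bad = true; bad_reason = "fewer read slots than quality bytes"; }
    if (!bad && qi != depth[i]) { bad = true; bad_reason = "depth does not match decodable read slots"; }
    if (bad) {
      bad_line[0] = i + 1;
      return List::create(_["counts"] = counts, _["bad_line"] = bad_line,
                          _["reason"] = bad_reason);
    }
  }
  return List::create(_["counts"] = counts, _["bad_line"] = bad_line,
                      _["reason"] = "");
}
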