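#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Sliding-window quality scan. Returns the number of leading bases to keep.
// Windows of `window` bases are scanned 5'->3'; at the first window whose
// mean quality drops below `threshold` (strict <), retention stops inside
// that window at the first base individually below the threshold. Reads
// shorter than one window are kept intact.
static int trim_keep_len(const int* q, int len, int window, double threshold) {
  if (len < window) return len;
  double need = threshold * window;  // compare sums, avoids division
  double tot = 0;
  for (int i = 0; i < window; ++i) tot += q[i];
  int fail = -1;
  if (tot < need) {
    fail = 0;
  } else {
    for (int i = window; i < len; ++i) {
      tot += q[i] - q[i - window];
      if (tot < need) { fail = i - window + 1; break; }
    }
  }
  if (fail < 0) return len;
  int keep = fail;
  while (keep < len && q[keep] >= threshold) ++keep;
  return keep;
}

// [[Rcpp::export]]
IntegerVector cpp_trim_batch(List quals, int window, double threshold) {
  int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector q = quals[i];
    out[i] = trim_keep_len(q.begin(), q.size(), window, threshold);
  }
  return out;
}

// Ungapped overlap merge of a forward read with the reverse-complemented
// mate. The largest overlap (searched from min(len_f, len_r) downward) whose
// mismatch fraction is <= max_mm wins; within the overlap the base with the
// higher Phred score is taken (tie -> forward base) and the quality is the
// max of the two. rev_quals are given in sequencing orientation and indexed
// back-to-front here.
// [[Rcpp::export]]
List cpp_merge_batch(CharacterVector fwd, List fwd_quals,
                     CharacterVector rev_rc, List rev_quals,
                     int min_overlap, double max_mm) {
  int n = fwd.size();
  CharacterVector mseq(n);
  List mqual(n);
  LogicalVector ok(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    const char* f = CHAR(STRING_ELT(fwd, r));
    const char* v = CHAR(STRING_ELT(rev_rc, r));
    IntegerVector fq = fwd_quals[r];
    IntegerVector rq = rev_quals[r];
    int lf = (int) std::strlen(f), lr = (int) std::strlen(v);
    int best = -1;
    int omax = lf < lr ? lf : lr;
    for (int o = omax; o >= min_overlap; --o) {
      int mm = 0, allowed = (int) std::floor(max_mm * o + 1e-9);
      const char* ft = f + (lf - o);
      bool fail = false;
      for (int i = 0; i < o; ++i) {
        if (ft[i] != v[i] && ++mm > allowed) { fail = true; break; }
      }
      if (!fail) { best = o; break; }
    }
    if (best < 0) { ok[r] = false; mseq[r] = NA_STRING; mqual[r] = R_NilValue; continue; }
    int o = best, lead = lf - o, tail = lr - o;
    int lm = lead + o + tail;
    buf.assign(lm, 'N');
    IntegerVector q(lm);
    for (int i = 0; i < lead; ++i) { buf[i] = f[i]; q[i] = fq[i]; }
    for (int i = 0; i < o; ++i) {
      int qf = fq[lead + i];
      int qr = rq[lr - 1 - i];  // reverse orientation: first rc base = last cycle
      char bf = f[lead + i], br = v[i];
      buf[lead + i] = (qr > qf) ? br : bf;
      q[lead + i] = qf > qr ? qf : qr;
    }
    for (int i = 0; i < tail; ++i) {
      buf[lead + o + i] = v[o + i];
      q[lead + o + i] = rq[lr - 1 - (o + i)];
    }
    ok[r] = true;
    mseq[r] = buf;
    mqual[r] = q;
  }
  return List::create(_["ok"] = ok, _["seq"] = mseq, _["qual"] = mqual);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// Mutational steps between sequences of unequal length. The sequences are
// globally aligned so as to maximise the number of matching columns; among
// maximal-match alignments the one minimising (mismatch columns + gap runs)
// is taken, and the step count is that penalty — each contiguous gap run
// counts as one step, each mismatch column as one. Encoded as a single
// Gotoh DP over the lexicographic score  matches * BIG - penalty.
// [[Rcpp::export]]
int cpp_align_steps(std::string a, std::string b) {
  const long long BIG = 1LL << 20;
  const long long NEG = LLONG_MIN / 4;
  int n = a.size(), m = b.size();
  std::vector<long long> M(m + 1), Ga(m + 1), Gb(m + 1),
      Mp(m + 1), Gap(m + 1), Gbp(m + 1);
  Mp[0] = 0; Gap[0] = NEG; Gbp[0] = NEG;
  for (int j = 1; j <= m; ++j) { Mp[j] = NEG; Gap[j] = NEG; Gbp[j] = -1; }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Gb[0] = NEG; Ga[0] = -1;
    for (int j = 1; j <= m; ++j) {
      long long col = (a[i - 1] == b[j - 1]) ? BIG : -1;
      long long diag = std::max(Mp[j - 1], std::max(Gap[j - 1], Gbp[j - 1]));
      M[j] = (diag <= NEG) ? NEG : diag + col;
      // gap in b, consuming a[i]: open (-1) unless extending Ga
      Ga[j] = std::max(Gap[j],
                       std::max(Mp[j] <= NEG ? NEG : Mp[j] - 1,
                                Gbp[j] <= NEG ? NEG : Gbp[j] - 1));
      // gap in a, consuming b[j]
      Gb[j] = std::max(Gb[j - 1],
                       std::max(M[j - 1] <= NEG ? NEG : M[j - 1] - 1,
                                Ga[j - 1] <= NEG ? NEG : Ga[j - 1] - 1));
    }
    std::swap(M, Mp); std::swap(Ga, Gap); std::swap(Gb, Gbp);
  }
  long long best = std::max(Mp[m], std::max(Gap[m], Gbp[m]));
  long long matches = (best + BIG - 1) / BIG;       // ceil: penalty < BIG
  if (best >= 0 && best % BIG == 0) matches = best / BIG;
  return (int)(matches * BIG - best);
}

// All-pairs step distances for a set of sequences (Hamming when lengths
// match, gapped steps otherwise).
// [[Rcpp::export]]
IntegerMatrix cpp_step_matrix(CharacterVector seqs) {
  int n = seqs.size();
  IntegerMatrix d(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int v = (s[i].size() == s[j].size()) ? cpp_hamming(s[i], s[j])
                                           : cpp_align_steps(s[i], s[j]);
      d(i, j) = v; d(j, i) = v;
    }
  return d;
}
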