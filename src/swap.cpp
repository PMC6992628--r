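#include <Rcpp.h>
using namespace Rcpp;

// Sequential 2x2 checkerboard swap attempts on a binary matrix.
// Uses R's RNG so results are reproducible under set.seed(). Failed
// attempts count (attempt-and-stay), which keeps the chain's stationary
// distribution uniform over the margin-preserving configurations.
// [[Rcpp::export(name = ".swap_attempts_cpp")]]
IntegerMatrix swap_attempts_cpp(IntegerMatrix m_in, int n_attempts) {
  IntegerMatrix m = clone(m_in);
  int nr = m.nrow(), nc = m.ncol();
  int accepted = 0;
  if (nr < 2 || nc < 2) {
    m.attr("accepted") = 0;
    return m;
  }
  for (int it = 0; it < n_attempts; ++it) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    int a = m(r1, c1), b = m(r1, c2), d = m(r2, c1), e = m(r2, c2);
    if (a == e && b == d && a != b) {
      m(r1, c1) = b;
      m(r2, c2) = b;
      m(r1, c2) = a;
      m(r2, c1) = a;
      ++accepted;
    }
  }
  m.attr("accepted") = accepted;
  return m;
}
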