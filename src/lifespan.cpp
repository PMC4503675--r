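#include <Rcpp.h>
using namespace Rcpp;

// Event-driven neutral ORF interruption simulator.
//
// The sequence is encoded as integers 0=A, 1=C, 2=G, 3=T. Waiting times
// between mutation events are exponential with total rate L*(mu+nu); each
// event picks a site uniformly. A point event substitutes the base (the
// transition partner weighted by kappa, transversions weight 1) and the ORF
// is interrupted when a non-terminal codon becomes a stop. An indel event
// interrupts when its length is not a multiple of 3 (in the default fixed
// length-1 mode every indel frameshifts). Loss of the terminal stop codon
// does not count as interruption. Returns the time of the first interruption
// in years, or +Inf when censored at the horizon.

static inline bool is_stop(int b1, int b2, int b3) {
  // TAA=3,0,0  TAG=3,0,2  TGA=3,2,0
  if (b1 != 3) return false;
  if (b2 == 0 && (b3 == 0 || b3 == 2)) return true;
  if (b2 == 2 && b3 == 0) return true;
  return false;
}

static double simulate_one(std::vector<int> seq, double mu, double nu,
                           double kappa, double horizon, bool terminal_stop,
                           int indel_mode, double geo_mean) {
  const int L = (int)seq.size();
  const int ncod = L / 3;
  const int last_cod = terminal_stop ? ncod - 1 : ncod; // codons checked for stops
  const double total = L * (mu + nu);
  if (total <= 0) return R_PosInf;
  const double p_indel = nu / (mu + nu);
  // geometric length parameter: length = 1 + Geom(p), mean = 1 + (1-p)/p
  const double geo_p = (geo_mean > 1.0) ? 1.0 / geo_mean : 1.0;

  double t = 0.0;
  for (;;) {
    t += R::rexp(1.0 / total);
    if (t > horizon) return R_PosInf;
    if (unif_rand() < p_indel) {
      if (indel_mode == 0) return t;           // fixed length 1: frameshift
      int len = 1 + (int)R::rgeom(geo_p);
      if (len % 3 != 0) return t;              // frameshifting indel
      // in-frame indel: no interruption; sequence effect ignored
      continue;
    }
    // point substitution
    int j = (int)(unif_rand() * L);
    if (j >= L) j = L - 1;
    int b = seq[j];
    int trans = (b + 2) % 4; // transition partner: A<->G, C<->T
    int tv1 = -1, tv2 = -1;
    for (int x = 0; x < 4; ++x) {
      if (x == b || x == trans) continue;
      if (tv1 < 0) tv1 = x; else tv2 = x;
    }
    double w = kappa + 2.0;
    double u = unif_rand() * w;
    int nb = (u < kappa) ? trans : (u < kappa + 1.0 ? tv1 : tv2);
    seq[j] = nb;
    int cod = j / 3;
    if (cod < last_cod) {
      if (is_stop(seq[3 * cod], seq[3 * cod + 1], seq[3 * cod + 2]))
        return t;                              // premature stop codon
    }
  }
}

// [[Rcpp::export]]
NumericVector orf_interruption_times_cpp(IntegerVector seq, double mu, double nu,
                                         double kappa, double horizon,
                                         bool terminal_stop, int indel_mode,
                                         double geo_mean, int n) {
  std::vector<int> s(seq.begin(), seq.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = simulate_one(s, mu, nu, kappa, horizon, terminal_stop,
                          indel_mode, geo_mean);
  return out;
}
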