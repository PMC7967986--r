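#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Self-contained xoshiro-free RNG: 64-bit Mersenne Twister with manual
// double generation, so that fits are bit-identical for a given seed
// across runs (R's RNG state is never touched).
namespace {

inline double unif01(std::mt19937_64 &rng) {
  // 53-bit uniform in [0, 1)
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

inline int sample_cat(const std::vector<double> &w, double total,
                      std::mt19937_64 &rng) {
  double u = unif01(rng) * total;
  double acc = 0.0;
  const int K = (int)w.size();
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u < acc) return k;
  }
  return K - 1;  // numerical guard
}

// Expand a docs x V count matrix into token streams.
void expand_tokens(const IntegerMatrix &counts, std::vector<int> &doc_of,
                   std::vector<int> &word_of, std::vector<int> &doc_start,
                   std::vector<int> &doc_len) {
  const int D = counts.nrow(), V = counts.ncol();
  long total = 0;
  for (int i = 0; i < D; ++i)
    for (int v = 0; v < V; ++v) total += counts(i, v);
  doc_of.reserve(total);
  word_of.reserve(total);
  doc_start.assign(D, 0);
  doc_len.assign(D, 0);
  for (int i = 0; i < D; ++i) {
    doc_start[i] = (int)doc_of.size();
    for (int v = 0; v < V; ++v) {
      int c = counts(i, v);
      for (int r = 0; r < c; ++r) {
        doc_of.push_back(i);
        word_of.push_back(v);
      }
    }
    doc_len[i] = (int)doc_of.size() - doc_start[i];
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".gibbs_lda_cpp")]]
List gibbs_lda_cpp(IntegerMatrix counts, int K, double alpha, double beta,
                   int n_sweeps, int n_burnin, int thin, int seed) {
  const int D = counts.nrow(), V = counts.ncol();
  std::vector<int> doc_of, word_of, doc_start, doc_len;
  expand_tokens(counts, doc_of, word_of, doc_start, doc_len);
  const long N = (long)doc_of.size();

  std::mt19937_64 rng((uint64_t)seed);

  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nkv((size_t)K * V, 0.0),
      nk(K, 0.0);

  // random initial assignments
  for (long t = 0; t < N; ++t) {
    int k = (int)(unif01(rng) * K);
    if (k >= K) k = K - 1;
    z[t] = k;
    ndk[(size_t)doc_of[t] * K + k] += 1.0;
    nkv[(size_t)k * V + word_of[t]] += 1.0;
    nk[k] += 1.0;
  }

  NumericMatrix theta_acc(D, K), phi_acc(K, V);
  int n_kept = 0;
  std::vector<double> w(K);
  const double Vbeta = V * beta;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (long t = 0; t < N; ++t) {
      const int d = doc_of[t], v = word_of[t], kold = z[t];
      ndk[(size_t)d * K + kold] -= 1.0;
      nkv[(size_t)kold * V + v] -= 1.0;
      nk[kold] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double p = (ndk[(size_t)d * K + k] + alpha) *
                   (nkv[(size_t)k * V + v] + beta) / (nk[k] + Vbeta);
        w[k] = p;
        total += p;
      }
      int knew = sample_cat(w, total, rng);
      z[t] = knew;
      ndk[(size_t)d * K + knew] += 1.0;
      nkv[(size_t)knew * V + v] += 1.0;
      nk[knew] += 1.0;
    }
    if (sweep >= n_burnin && ((sweep - n_burnin) % thin == 0)) {
      ++n_kept;
      for (int i = 0; i < D; ++i) {
        const double denom = doc_len[i] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(i, k) += (ndk[(size_t)i * K + k] + alpha) / denom;
      }
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + Vbeta;
        for (int v = 0; v < V; ++v)
          phi_acc(k, v) += (nkv[(size_t)k * V + v] + beta) / denom;
      }
    }
    if (sweep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  if (n_kept == 0) stop("no retained sweeps: check n_sweeps/n_burnin/thin");
  for (int i = 0; i < D; ++i)
    for (int k = 0; k < K; ++k) theta_acc(i, k) /= n_kept;
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi_acc(k, v) /= n_kept;

  IntegerVector zout(N);
  for (long t = 0; t < N; ++t) zout[t] = z[t] + 1;

  return List::create(_["theta"] = theta_acc, _["phi"] = phi_acc,
                      _["assignments"] = zout, _["n_kept"] = n_kept);
}

//' @noRd
// [[Rcpp::export(name = ".gibbs_fold_in_cpp")]]
NumericMatrix gibbs_fold_in_cpp(IntegerMatrix counts, NumericMatrix phi,
                                double alpha, int n_sweeps, int n_burnin,
                                int thin, int seed) {
  const int D = counts.nrow(), V = counts.ncol(), K = phi.nrow();
  if (phi.ncol() != V) stop("phi/counts OTU-axis mismatch");
  std::vector<int> doc_of, word_of, doc_start, doc_len;
  expand_tokens(counts, doc_of, word_of, doc_start, doc_len);
  const long N = (long)doc_of.size();

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0);
  for (long t = 0; t < N; ++t) {
    int k = (int)(unif01(rng) * K);
    if (k >= K) k = K - 1;
    z[t] = k;
    ndk[(size_t)doc_of[t] * K + k] += 1.0;
  }

  NumericMatrix theta_acc(D, K);
  int n_kept = 0;
  std::vector<double> w(K);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (long t = 0; t < N; ++t) {
      const int d = doc_of[t], v = word_of[t], kold = z[t];
      ndk[(size_t)d * K + kold] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double p = (ndk[(size_t)d * K + k] + alpha) * phi(k, v);
        w[k] = p;
        total += p;
      }
      int knew = sample_cat(w, total, rng);
      z[t] = knew;
      ndk[(size_t)d * K + knew] += 1.0;
    }
    if (sweep >= n_burnin && ((sweep - n_burnin) % thin == 0)) {
      ++n_kept;
      for (int i = 0; i < D; ++i) {
        const double denom = doc_len[i] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(i, k) += (ndk[(size_t)i * K + k] + alpha) / denom;
      }
    }
    if (sweep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_kept == 0) stop("no retained sweeps: check n_sweeps/n_burnin/thin");
  for (int i = 0; i < D; ++i)
    for (int k = 0; k < K; ++k) theta_acc(i, k) /= n_kept;
  return theta_acc;
}
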