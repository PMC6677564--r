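#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Single-population coalescent with piecewise-constant diploid size and a
// generalized stepwise mutation model (GSM) on microsatellite repeat counts.
//
// Time runs backwards in generations. Epochs are given as ascending start
// times (first must be 0) with a diploid effective size per epoch; the last
// epoch extends to infinity. Pairwise coalescence rate within an epoch of
// size N is 1/(2N) per generation.
//
// Mutations on a branch of length L are Poisson(mu * L). Each mutation moves
// the allele by +/-(1 + G) repeat units with G ~ Geometric(p) on {0,1,...}
// and equiprobable sign. The summed displacement over the m mutations of a
// branch is sampled in O(1) draws: m_up ~ Binomial(m, 1/2), and the summed
// step sizes of the upward (resp. downward) mutations are
// m_up + NegBinomial(m_up, p) (a sum of m_up independent Geometric(p) terms).
// Allele-range bounds are enforced by folding (reflecting) each node's value
// into [amin, amax] before its descendant branches evolve.

static void build_tree(int n, const NumericVector &epoch_start,
                       const NumericVector &epoch_N,
                       std::vector<int> &parent, std::vector<double> &blen) {
  int n_nodes = 2 * n - 1;
  parent.assign(n_nodes, -1);
  blen.assign(n_nodes, 0.0);
  std::vector<double> node_time(n_nodes, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int k = n, next_node = n, ep = 0;
  int n_ep = epoch_start.size();
  double t = 0.0;
  while (k > 1) {
    double N = epoch_N[ep];
    double rate = (double)k * (k - 1) / 2.0 / (2.0 * N);
    double w = R::exp_rand() / rate;
    double ep_end = (ep + 1 < n_ep) ? epoch_start[ep + 1] : R_PosInf;
    if (t + w > ep_end) { t = ep_end; ++ep; continue; }
    t += w;
    int i = (int)std::floor(R::unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)std::floor(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    parent[a] = next_node; parent[b] = next_node;
    blen[a] = t - node_time[a]; blen[b] = t - node_time[b];
    node_time[next_node] = t;
    // replace the two children by the new node in the active list
    int hi = std::max(i, j), lo = std::min(i, j);
    active[lo] = next_node;
    active[hi] = active[k - 1];
    ++next_node; --k;
  }
  (void)node_time;
}

// exact sawtooth fold of an integral value into [amin, amax]
static inline double fold_into(double x, double amin, double amax) {
  if (amax <= amin) return amin;
  long long width = (long long)(amax - amin);
  long long period = 2 * width;
  long long r = ((long long)x - (long long)amin) % period;
  if (r < 0) r += period;
  if (r > width) r = period - r;
  return amin + (double)r;
}

static inline double branch_displacement(double m, double p) {
  if (m <= 0) return 0.0;
  double m_up = R::rbinom(m, 0.5);
  double m_dn = m - m_up;
  double up = m_up, dn = m_dn;
  if (m_up > 0) up += R::rnbinom(m_up, p);
  if (m_dn > 0) dn += R::rnbinom(m_dn, p);
  return up - dn;
}

// Simulate tip allele sizes (repeat units) for one locus.
// [[Rcpp::export]]
IntegerVector cpp_sim_locus(int n_genes, NumericVector epoch_start,
                            NumericVector epoch_N, double mu, double p_gsm,
                            int amin, int amax, bool reflect) {
  if (n_genes < 2) stop("n_genes must be >= 2");
  std::vector<int> parent; std::vector<double> blen;
  build_tree(n_genes, epoch_start, epoch_N, parent, blen);
  int n_nodes = 2 * n_genes - 1;
  std::vector<double> allele(n_nodes);
  allele[n_nodes - 1] = std::floor((amin + amax) / 2.0); // root at range midpoint
  for (int v = n_nodes - 2; v >= 0; --v) {
    double m = (mu > 0 && blen[v] > 0) ? R::rpois(mu * blen[v]) : 0.0;
    double x = allele[parent[v]] + branch_displacement(m, p_gsm);
    if (reflect) x = fold_into(x, (double)amin, (double)amax);
    else x = std::min(std::max(x, (double)amin), (double)amax);
    allele[v] = x;
  }
  IntegerVector out(n_genes);
  for (int i = 0; i < n_genes; ++i) out[i] = (int)std::lround(allele[i]);
  return out;
}

// Height (TMRCA) of a simulated genealogy, in generations.
// [[Rcpp::export]]
double cpp_sim_tmrca(int n_genes, NumericVector epoch_start,
                     NumericVector epoch_N) {
  std::vector<int> parent; std::vector<double> blen;
  build_tree(n_genes, epoch_start, epoch_N, parent, blen);
  // height = time of the root = sum of branch lengths along any tip-root path
  double h = 0.0; int v = 0;
  while (parent[v] >= 0) { h += blen[v]; v = parent[v]; }
  return h;
}

static void locus_stats(const IntegerVector &sizes, double *A, double *GD,
                        double *VAR, double *M) {
  int n = sizes.size();
  std::map<int, int> tab;
  double mean = 0.0;
  int mn = sizes[0], mx = sizes[0];
  for (int i = 0; i < n; ++i) {
    tab[sizes[i]]++;
    mean += sizes[i];
    if (sizes[i] < mn) mn = sizes[i];
    if (sizes[i] > mx) mx = sizes[i];
  }
  mean /= n;
  double sumsq_p = 0.0, var = 0.0;
  for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
    double p = (double)it->second / n;
    sumsq_p += p * p;
  }
  for (int i = 0; i < n; ++i) var += (sizes[i] - mean) * (sizes[i] - mean);
  var /= n; // denominator n (population variance over gene copies)
  *A = (double)tab.size();
  *GD = (n > 1) ? (double)n / (n - 1) * (1.0 - sumsq_p) : 0.0;
  *VAR = var;
  *M = (double)tab.size() / ((double)(mx - mn) + 1.0);
}

// Simulate a full multi-locus dataset and return the four ABC summary
// statistics averaged across loci:
// (mean #alleles, mean unbiased gene diversity, mean allele-size variance,
//  mean Garza-Williamson M).
// [[Rcpp::export]]
NumericVector cpp_sim_stats(int n_genes, NumericVector epoch_start,
                            NumericVector epoch_N, NumericVector mu,
                            NumericVector p_gsm, IntegerVector amin,
                            IntegerVector amax, bool reflect) {
  int L = mu.size();
  double sA = 0, sGD = 0, sV = 0, sM = 0;
  for (int l = 0; l < L; ++l) {
    IntegerVector sizes = cpp_sim_locus(n_genes, epoch_start, epoch_N, mu[l],
                                        p_gsm[l], amin[l], amax[l], reflect);
    double A, GD, V, M;
    locus_stats(sizes, &A, &GD, &V, &M);
    sA += A; sGD += GD; sV += V; sM += M;
  }
  return NumericVector::create(sA / L, sGD / L, sV / L, sM / L);
}

// Simulate tip allele sizes for every locus at once; returns an
// (n_genes x n_loci) integer matrix of repeat counts.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_genes(int n_genes, NumericVector epoch_start,
                            NumericVector epoch_N, NumericVector mu,
                            NumericVector p_gsm, IntegerVector amin,
                            IntegerVector amax, bool reflect) {
  int L = mu.size();
  IntegerMatrix out(n_genes, L);
  for (int l = 0; l < L; ++l) {
    IntegerVector sizes = cpp_sim_locus(n_genes, epoch_start, epoch_N, mu[l],
                                        p_gsm[l], amin[l], amax[l], reflect);
    for (int i = 0; i < n_genes; ++i) out(i, l) = sizes[i];
  }
  return out;
}
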