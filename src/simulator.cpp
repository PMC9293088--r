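// Individual-based metapopulation genetic simulator on a dendritic network.
//
// State convention shared with the R wrappers:
//   geno : integer matrix, one row per individual, 2 * n_loci columns
//          (columns 2l-1, 2l hold the two allele copies of locus l),
//          allele states are integers in 1..n_states
//   node : 1-based patch index per individual
//   sex  : 1 = female, 0 = male
//
// All randomness goes through R's RNG (unif_rand / R::rpois), so results are
// reproducible with set.seed() from the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int runif_int(int n) {
  // uniform integer in 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export(name = ".cpp_reproduction")]]
List cpp_reproduction(IntegerMatrix geno, IntegerVector node, IntegerVector sex,
                      IntegerVector K, double lambda0) {
  const int n_ind = geno.nrow();
  const int n_col = geno.ncol();
  const int n_loci = n_col / 2;
  const int n_nodes = K.size();

  std::vector<int> N(n_nodes, 0);
  std::vector< std::vector<int> > males(n_nodes);
  for (int i = 0; i < n_ind; i++) {
    int p = node[i] - 1;
    N[p]++;
    if (sex[i] == 0) males[p].push_back(i);
  }

  std::vector<int> off_mother, off_father, off_node, off_sex;
  for (int i = 0; i < n_ind; i++) {
    if (sex[i] != 1) continue;                  // mothers only
    int p = node[i] - 1;
    if (males[p].empty()) continue;             // no mate available locally
    // Beverton-Holt expected brood size; N counted before reproduction
    double mean = 2.0 * lambda0 /
      (1.0 + (lambda0 - 1.0) * (double)N[p] / (double)K[p]);
    int noff = (int)R::rpois(mean);
    for (int o = 0; o < noff; o++) {
      int father = males[p][runif_int((int)males[p].size())];
      off_mother.push_back(i);
      off_father.push_back(father);
      off_node.push_back(node[i]);
      off_sex.push_back(unif_rand() < 0.5 ? 1 : 0);
    }
  }

  const int n_off = (int)off_mother.size();
  IntegerMatrix g(n_off, n_col);
  IntegerVector nd(n_off), sx(n_off);
  for (int o = 0; o < n_off; o++) {
    int mo = off_mother[o], fa = off_father[o];
    for (int l = 0; l < n_loci; l++) {
      g(o, 2 * l)     = geno(mo, 2 * l + (unif_rand() < 0.5 ? 0 : 1));
      g(o, 2 * l + 1) = geno(fa, 2 * l + (unif_rand() < 0.5 ? 0 : 1));
    }
    nd[o] = off_node[o];
    sx[o] = off_sex[o];
  }
  return List::create(_["geno"] = g, _["node"] = nd, _["sex"] = sx);
}

// mut_model: 1 = stepwise (+/-1, reflecting at 1 and n_states),
//            2 = random (uniform over all states, resampling allowed)
// [[Rcpp::export(name = ".cpp_mutation")]]
IntegerMatrix cpp_mutation(IntegerMatrix geno, double mu, int mut_model,
                           int n_states) {
  IntegerMatrix g = clone(geno);
  const int n = g.nrow(), m = g.ncol();
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < m; j++) {
      if (unif_rand() >= mu) continue;
      int s = g(i, j);
      if (mut_model == 1) {
        if (s <= 1) s = 2;
        else if (s >= n_states) s = n_states - 1;
        else s += (unif_rand() < 0.5) ? 1 : -1;
      } else {
        s = 1 + runif_int(n_states);
      }
      g(i, j) = s;
    }
  }
  return g;
}

// down: 1-based downstream neighbour per node, 0 for the outlet
// up:   list of 1-based upstream neighbour vectors per node
// Returns new node assignment and a survival flag per individual
// (dispersal mortality m applies to emigrants only).
// [[Rcpp::export(name = ".cpp_dispersal")]]
List cpp_dispersal(IntegerVector node, double d, double W, double m,
                   IntegerVector down, List up) {
  const int n_ind = node.size();
  const int n_nodes = down.size();
  std::vector< std::vector<int> > upv(n_nodes);
  for (int p = 0; p < n_nodes; p++) {
    IntegerVector u = up[p];
    for (int j = 0; j < u.size(); j++) upv[p].push_back(u[j]);
  }

  IntegerVector new_node = clone(node);
  LogicalVector alive(n_ind, true);
  for (int i = 0; i < n_ind; i++) {
    if (unif_rand() >= d) continue;             // stays at the natal node
    int p = node[i] - 1;
    double w_down = (down[p] > 0) ? 1.0 : 0.0;
    double tot = w_down + W * (double)upv[p].size();
    if (tot <= 0.0) continue;                   // nowhere to go: stays
    double u = unif_rand() * tot;
    if (u < w_down) {
      new_node[i] = down[p];
    } else {
      int k = (int)((u - w_down) / W);
      if (k >= (int)upv[p].size()) k = (int)upv[p].size() - 1;
      new_node[i] = upv[p][k];
    }
    if (m > 0.0 && unif_rand() < m) alive[i] = false;
  }
  return List::create(_["node"] = new_node, _["alive"] = alive);
}

// Mean expected heterozygosity over loci from metapopulation-pooled allele
// frequencies (plain gene diversity 1 - sum p^2); used for the trajectory.
static double pooled_mean_he(const IntegerMatrix& geno, int n_loci,
                             int n_states) {
  const int n = geno.nrow();
  if (n == 0) return NA_REAL;
  double tot = 0.0;
  std::vector<int> cnt(n_states);
  for (int l = 0; l < n_loci; l++) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; i++) {
      cnt[geno(i, 2 * l) - 1]++;
      cnt[geno(i, 2 * l + 1) - 1]++;
    }
    double ssq = 0.0, N2 = 2.0 * n;
    for (int a = 0; a < n_states; a++) {
      double p = cnt[a] / N2;
      ssq += p * p;
    }
    tot += 1.0 - ssq;
  }
  return tot / n_loci;
}

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(IntegerVector K, IntegerVector down, List up,
             double d, double W, double mu, double lambda0, double m,
             int n_loci, int n_states, int mut_model, int generations,
             int traj_every) {
  const int n_nodes = K.size();

  // initialize every node at carrying capacity, uniform alleles and sexes
  int n0 = 0;
  for (int p = 0; p < n_nodes; p++) n0 += K[p];
  IntegerMatrix geno(n0, 2 * n_loci);
  IntegerVector node(n0), sex(n0);
  {
    int i = 0;
    for (int p = 0; p < n_nodes; p++) {
      for (int k = 0; k < K[p]; k++, i++) {
        node[i] = p + 1;
        sex[i] = unif_rand() < 0.5 ? 1 : 0;
        for (int j = 0; j < 2 * n_loci; j++) geno(i, j) = 1 + runif_int(n_states);
      }
    }
  }

  std::vector<int> tr_gen;
  std::vector<double> tr_n, tr_he;
  bool extinct = false;
  int t = 0;
  for (t = 1; t <= generations; t++) {
    List off = cpp_reproduction(geno, node, sex, K, lambda0);
    IntegerMatrix g = off["geno"];
    IntegerVector nd = off["node"];
    IntegerVector sx = off["sex"];
    if (g.nrow() == 0) { extinct = true; break; }
    g = cpp_mutation(g, mu, mut_model, n_states);
    List disp = cpp_dispersal(nd, d, W, m, down, up);
    IntegerVector nd2 = disp["node"];
    LogicalVector alive = disp["alive"];
    int n_alive = 0;
    for (int i = 0; i < alive.size(); i++) if (alive[i]) n_alive++;
    if (n_alive == 0) { extinct = true; break; }
    IntegerMatrix g2(n_alive, 2 * n_loci);
    IntegerVector nd3(n_alive), sx2(n_alive);
    for (int i = 0, k = 0; i < alive.size(); i++) {
      if (!alive[i]) continue;
      for (int j = 0; j < 2 * n_loci; j++) g2(k, j) = g(i, j);
      nd3[k] = nd2[i];
      sx2[k] = sx[i];
      k++;
    }
    geno = g2; node = nd3; sex = sx2;
    if (t % traj_every == 0 || t == generations) {
      tr_gen.push_back(t);
      tr_n.push_back((double)geno.nrow());
      tr_he.push_back(pooled_mean_he(geno, n_loci, n_states));
    }
  }

  return List::create(
    _["geno"] = geno, _["node"] = node, _["sex"] = sex,
    _["trajectory"] = DataFrame::create(
        _["generation"] = wrap(tr_gen), _["total_n"] = wrap(tr_n),
        _["mean_he"] = wrap(tr_he)),
    _["extinct"] = extinct,
    _["last_generation"] = extinct ? t : generations);
}
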