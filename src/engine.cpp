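#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Asynchronous per-cell update engine for the aggregative-multicellularity
// lattice model. State is kept in flat vectors indexed by 0-based linear
// site index (column-major, matching R matrices: site = col * M + row).
//
// Association links are stored as an 8-bit mask per site: bit d set means
// "linked to the Moore neighbour in direction d". Directions are ordered so
// that the opposite of d is 7 - d, which keeps the symmetric reciprocal bit
// computable without lookup.
//
// All randomness flows through R's RNG (unif_rand), in a fixed draw order
// per update, so that runs replay bit-exactly under set.seed() and so that
// the pure-R reference implementation (R/update.R) can consume the identical
// stream. Any change to the draw order here must be mirrored there.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

enum Mechanism {
  MECH_NONE = 0,
  MECH_RANDOM_DISPERSION = 1,
  MECH_RANDOM_REFUGE = 2,
  MECH_RANDOM_FRAGMENTATION = 3,
  MECH_AGG_DISPERSION = 4,
  MECH_AGG_PROPAGULE = 5
};

enum Termination {
  TERM_T_REACHED = 1,
  TERM_EXTINCTION = 2,
  TERM_NO_COLONIZATION = 3,
  TERM_COOP_FIXATION = 4
};

struct Engine {
  int M, ncell;
  std::vector<int> occ;       // 0 empty, 1 cooperator, 2 defector
  std::vector<double> energy;
  std::vector<double> resource;
  std::vector<int> links;     // 8-bit adjacency mask
  std::vector<int> na;        // incrementally maintained associated-neighbour count
  std::vector<int> occ_list;  // occupied sites; swap-remove order
  std::vector<int> pos;       // site -> index in occ_list, -1 if empty
  int n_coop, n_def, n_linked;
  double total_res;

  // parameters
  double cC, cD, d, S, O, m, AC, AD, Dp, uptake, Rthr, s;
  bool pred_on, dissoc_all;

  // per-update bookkeeping for the outcome record / conservation oracle
  double sys_loss;

  int neighbor(int site, int dir) const {
    int r = site % M + DR[dir];
    int c = site / M + DC[dir];
    if (r < 0) r += M; else if (r >= M) r -= M;
    if (c < 0) c += M; else if (c >= M) c -= M;
    return c * M + r;
  }

  void set_params(const List& par) {
    cC = as<double>(par["c_C"]);
    cD = as<double>(par["c_D"]);
    d = as<double>(par["d"]);
    S = as<double>(par["S"]);
    O = as<double>(par["O"]);
    m = as<double>(par["m"]);
    AC = as<double>(par["A_C"]);
    AD = as<double>(par["A_D"]);
    Dp = as<double>(par["D"]);
    uptake = as<double>(par["uptake"]);
    Rthr = as<double>(par["R"]);
    pred_on = as<bool>(par["predation_on"]);
    s = pred_on ? as<double>(par["s_num"]) : 0.0;
    dissoc_all = as<bool>(par["dissoc_all"]);
  }

  void load_state(const IntegerVector& occ_, const NumericVector& energy_,
                  const NumericVector& resource_, const IntegerVector& links_,
                  int M_) {
    M = M_;
    ncell = M * M;
    occ.assign(occ_.begin(), occ_.end());
    energy.assign(energy_.begin(), energy_.end());
    resource.assign(resource_.begin(), resource_.end());
    links.assign(links_.begin(), links_.end());
    rebuild_index();
  }

  // canonical occupied-list order: increasing linear site index
  void rebuild_index() {
    occ_list.clear();
    pos.assign(ncell, -1);
    na.assign(ncell, 0);
    n_coop = n_def = n_linked = 0;
    total_res = 0.0;
    for (int i = 0; i < ncell; ++i) {
      total_res += resource[i];
      if (occ[i] != 0) {
        pos[i] = (int)occ_list.size();
        occ_list.push_back(i);
        if (occ[i] == 1) ++n_coop; else ++n_def;
        na[i] = __builtin_popcount(links[i]);
        if (links[i] != 0) ++n_linked;
      }
    }
  }

  int population() const { return (int)occ_list.size(); }

  void add_link(int a, int dir) {
    int b = neighbor(a, dir);
    if (links[a] == 0) ++n_linked;
    if (links[b] == 0) ++n_linked;
    links[a] |= (1 << dir);
    links[b] |= (1 << (7 - dir));
    ++na[a]; ++na[b];
  }

  void remove_link(int a, int dir) {
    int b = neighbor(a, dir);
    links[a] &= ~(1 << dir);
    links[b] &= ~(1 << (7 - dir));
    --na[a]; --na[b];
    if (links[a] == 0) --n_linked;
    if (links[b] == 0) --n_linked;
  }

  void clear_links(int a) {
    int mask = links[a];
    if (mask == 0) return;
    for (int dir = 0; dir < 8; ++dir) {
      if (mask & (1 << dir)) {
        int b = neighbor(a, dir);
        links[b] &= ~(1 << (7 - dir));
        --na[b];
        if (links[b] == 0) --n_linked;
      }
    }
    links[a] = 0;
    na[a] = 0;
    --n_linked;
  }

  void add_cell(int site, int kind, double e) {
    occ[site] = kind;
    energy[site] = e;
    pos[site] = (int)occ_list.size();
    occ_list.push_back(site);
    if (kind == 1) ++n_coop; else ++n_def;
  }

  void remove_cell(int site) {
    sys_loss += energy[site];
    clear_links(site);
    if (occ[site] == 1) --n_coop; else --n_def;
    occ[site] = 0;
    energy[site] = 0.0;
    int p = pos[site];
    int last = (int)occ_list.size() - 1;
    int lastsite = occ_list[last];
    occ_list[p] = lastsite;
    pos[lastsite] = p;
    occ_list.pop_back();
    pos[site] = -1;
  }

  void move_cell(int from, int to) {
    occ[to] = occ[from];
    energy[to] = energy[from];
    occ[from] = 0;
    energy[from] = 0.0;
    int p = pos[from];
    occ_list[p] = to;
    pos[to] = p;
    pos[from] = -1;
  }

  // One asynchronous update. Sub-step order is fixed:
  // metabolism -> consume -> divide -> associate -> dissociate -> move -> predation.
  // Returns false if the lattice was empty (no-op update).
  bool update_one(double* rec) {
    sys_loss = 0.0;
    int n = population();
    if (n == 0) return false;
    int site = occ_list[(int)(unif_rand() * n)];
    int kind = occ[site];
    if (rec) { rec[0] = site; rec[1] = kind; }

    // metabolism: constant cost by type; energy at or below zero is starvation
    double c = (kind == 1) ? cC : cD;
    energy[site] -= c;
    sys_loss += c;
    if (energy[site] <= 0.0) {
      remove_cell(site);  // books the (non-positive) remainder; total loss = pre-update energy
      if (rec) { rec[9] = 1; rec[11] = sys_loss; }
      return true;
    }

    // consumption: capped transfer from the site, strict conservation
    double take = std::min(resource[site], uptake);
    if (take > 0.0) {
      resource[site] -= take;
      energy[site] += take;
      total_res -= take;
    }
    if (rec) rec[2] = take;

    // division: direction first, then occupancy decides S vs S*O
    if (energy[site] > d) {
      int dir = (int)(unif_rand() * 8);
      int tgt = neighbor(site, dir);
      bool fire;
      bool overwrite = (occ[tgt] != 0);
      if (!overwrite) {
        fire = unif_rand() < S;
      } else {
        fire = unif_rand() < S * O;
      }
      if (fire) {
        if (overwrite) {
          remove_cell(tgt);
          if (rec) { rec[4] = 1; rec[10] = tgt; }
        }
        double e2 = energy[site] / 2.0;
        energy[site] = e2;
        add_cell(tgt, kind, e2);
        if (rec) { rec[3] = 1; rec[5] = tgt; }
      }
    }

    // association: cooperators initiate; one uniformly chosen occupied,
    // not-yet-linked Moore neighbour accepts
    bool participated = false;
    double A = (kind == 1) ? AC : AD;
    if (A > 0.0 && unif_rand() < A) {
      int cand[8];
      int k = 0;
      for (int dir = 0; dir < 8; ++dir) {
        int b = neighbor(site, dir);
        if (occ[b] != 0 && !(links[site] & (1 << dir))) cand[k++] = dir;
      }
      if (k > 0) {
        int dir = cand[(int)(unif_rand() * k)];
        add_link(site, dir);
        participated = true;
        if (rec) rec[6] = neighbor(site, dir);
      }
    }

    // dissociation: skipped if the cell took part in association this update
    if (!participated && links[site] != 0) {
      if (unif_rand() < Dp) {
        if (dissoc_all) {
          clear_links(site);
        } else {
          int j = (int)(unif_rand() * na[site]);
          int seen = 0, mask = links[site];
          for (int dir = 0; dir < 8; ++dir) {
            if (mask & (1 << dir)) {
              if (seen == j) { remove_link(site, dir); break; }
              ++seen;
            }
          }
        }
        if (rec) rec[7] = 1;
      }
    }

    // movement: unassociated cells only; 9 equally likely options (8 dirs + stay);
    // an occupied target means the cell stays; relocation costs m
    if (links[site] == 0) {
      int choice = (int)(unif_rand() * 9);
      if (choice < 8) {
        int tgt = neighbor(site, choice);
        if (occ[tgt] == 0) {
          move_cell(site, tgt);
          site = tgt;
          energy[site] -= m;
          sys_loss += m;
          if (rec) rec[8] = tgt;
          if (energy[site] <= 0.0) {
            remove_cell(site);  // books the non-positive remainder after paying m

            if (rec) { rec[9] = 1; rec[11] = sys_loss; }
            return true;
          }
        }
      }
    }

    // predation: size-dependent selection P = 1 / (N_a + 2)^s
    if (pred_on) {
      double P = std::pow((double)(na[site] + 2), -s);
      if (unif_rand() < P) {
        remove_cell(site);
        if (rec) rec[9] = 2;
      }
    }
    if (rec) rec[11] = sys_loss;
    return true;
  }
};

static void fill_rec_defaults(double* rec) {
  rec[0] = -1; rec[1] = 0; rec[2] = 0; rec[3] = 0; rec[4] = 0;
  rec[5] = -1; rec[6] = -1; rec[7] = 0; rec[8] = -1; rec[9] = 0;
  rec[10] = -1; rec[11] = 0;
}

// Run `n` asynchronous updates with no scarcity handling; for unit tests and
// step-level oracles. Inputs are copied, not modified.
// [[Rcpp::export]]
List engine_steps(IntegerVector occ, NumericVector energy, NumericVector resource,
                  IntegerVector links, List par, int n, bool record = false) {
  Engine E;
  E.set_params(par);
  E.load_state(occ, energy, resource, links, as<int>(par["M"]));

  NumericMatrix outcomes;
  if (record) outcomes = NumericMatrix(n, 12);
  double rec[12];
  for (int t = 0; t < n; ++t) {
    fill_rec_defaults(rec);
    E.update_one(record ? rec : (double*)0);
    if (record) for (int j = 0; j < 12; ++j) outcomes(t, j) = rec[j];
  }

  List out = List::create(
    _["occ"] = IntegerVector(E.occ.begin(), E.occ.end()),
    _["energy"] = NumericVector(E.energy.begin(), E.energy.end()),
    _["resource"] = NumericVector(E.resource.begin(), E.resource.end()),
    _["links"] = IntegerVector(E.links.begin(), E.links.end()),
    _["na"] = IntegerVector(E.na.begin(), E.na.end()),
    _["n_coop"] = E.n_coop,
    _["n_def"] = E.n_def,
    _["n_linked"] = E.n_linked,
    _["total_resource"] = E.total_res);
  if (record) {
    colnames(outcomes) = CharacterVector::create(
      "site", "kind", "consumed", "divided", "overwrote", "daughter_site",
      "assoc_site", "dissociated", "moved_to", "death", "victim_site",
      "sys_loss");
    out["outcomes"] = outcomes;
  }
  return out;
}

struct TraceBuf {
  std::vector<double> update, n_coop, n_def, total_resource, n_assoc;
  std::vector<int> event;
  double last_t = -1.0;
  void push(double t, int nc, int nd, double res, int nl, int ev) {
    if (!update.empty() && update.back() == t) {
      // overwrite same-update row (colonization supersedes a scheduled sample)
      n_coop.back() = nc; n_def.back() = nd; total_resource.back() = res;
      n_assoc.back() = nl;
      if (ev != 0) event.back() = ev;
      return;
    }
    update.push_back(t); n_coop.push_back(nc); n_def.push_back(nd);
    total_resource.push_back(res); n_assoc.push_back(nl); event.push_back(ev);
  }
};

// Full simulation loop: updates, exact scarcity detection, colonization via
// an R callback, early stopping, trace sampling. Inputs are copied.
// [[Rcpp::export]]
List engine_run(IntegerVector occ, NumericVector energy, NumericVector resource,
                IntegerVector links, List par, Function colonize_cb) {
  Engine E;
  E.set_params(par);
  E.load_state(occ, energy, resource, links, as<int>(par["M"]));

  double T = as<double>(par["T"]);
  double trace_every = as<double>(par["trace_every"]);
  int mech = as<int>(par["mech"]);
  int min_pop_frag = as<int>(par["min_pop_for_fragmentation"]);
  bool require_coop = as<bool>(par["require_cooperator"]);
  bool stop_no_col = as<bool>(par["early_stop_no_colonization"]);
  bool stop_coop_fix = as<bool>(par["early_stop_cooperator_fixation"]);

  TraceBuf tr;
  tr.push(0.0, E.n_coop, E.n_def, E.total_res, E.n_linked, 0);

  int term = TERM_T_REACHED;
  int last_nc = E.n_coop, last_nd = E.n_def;
  int n_colonizations = 0;
  double t = 0.0;
  double next_sample = trace_every;

  while (t < T) {
    if (E.population() == 0) { term = TERM_EXTINCTION; break; }
    if (stop_coop_fix && E.n_def == 0 && E.n_coop > 0) {
      term = TERM_COOP_FIXATION;
      break;
    }
    t += 1.0;
    E.update_one((double*)0);
    if (E.population() > 0) { last_nc = E.n_coop; last_nd = E.n_def; }

    if (E.total_res < E.Rthr && mech != MECH_NONE) {
      int pop = E.population();
      bool can = pop > 0 &&
        (!require_coop || E.n_coop > 0) &&
        (mech != MECH_RANDOM_FRAGMENTATION || pop > min_pop_frag);
      if (can) {
        PutRNGstate();
        List nh = colonize_cb(
          IntegerVector(E.occ.begin(), E.occ.end()),
          IntegerVector(E.links.begin(), E.links.end()));
        GetRNGstate();
        IntegerVector nocc = nh["occ"];
        NumericVector nen = nh["energy"];
        NumericVector nres = nh["resource"];
        IntegerVector nlinks = nh["links"];
        E.occ.assign(nocc.begin(), nocc.end());
        E.energy.assign(nen.begin(), nen.end());
        E.resource.assign(nres.begin(), nres.end());
        E.links.assign(nlinks.begin(), nlinks.end());
        E.rebuild_index();
        ++n_colonizations;
        last_nc = E.n_coop; last_nd = E.n_def;
        tr.push(t, E.n_coop, E.n_def, E.total_res, E.n_linked, mech);
      } else if (pop > 0 && stop_no_col) {
        term = TERM_NO_COLONIZATION;
        break;
      }
    }

    if (t >= next_sample) {
      tr.push(t, E.n_coop, E.n_def, E.total_res, E.n_linked, 0);
      next_sample += trace_every;
    }
  }

  tr.push(t, E.n_coop, E.n_def, E.total_res, E.n_linked, 0);

  return List::create(
    _["trace_update"] = NumericVector(tr.update.begin(), tr.update.end()),
    _["trace_n_coop"] = NumericVector(tr.n_coop.begin(), tr.n_coop.end()),
    _["trace_n_def"] = NumericVector(tr.n_def.begin(), tr.n_def.end()),
    _["trace_total_resource"] =
      NumericVector(tr.total_resource.begin(), tr.total_resource.end()),
    _["trace_n_associated"] = NumericVector(tr.n_assoc.begin(), tr.n_assoc.end()),
    _["trace_event"] = IntegerVector(tr.event.begin(), tr.event.end()),
    _["occ"] = IntegerVector(E.occ.begin(), E.occ.end()),
    _["energy"] = NumericVector(E.energy.begin(), E.energy.end()),
    _["resource"] = NumericVector(E.resource.begin(), E.resource.end()),
    _["links"] = IntegerVector(E.links.begin(), E.links.end()),
    _["termination"] = term,
    _["updates"] = t,
    _["last_n_coop"] = last_nc,
    _["last_n_def"] = last_nd,
    _["n_colonizations"] = n_colonizations);
}
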