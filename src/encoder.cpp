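// Forward and backward passes of the meta-path fusion encoder.
//
// Per target node u the stack is:
//   h_u^p  = mean of transformed node vectors along instance p
//   e_p    = ReLU(att_inst[type] . [h_u || h_u^p])
//   e'_p   = softmax over the instances of one (target, type) group
//   h_u^P  = sigmoid(sum_p e'_p h_u^p)
//   s_P    = ReLU(att_type[P] . h_u^P)
//   w_P    = softmax over the types present for u
//   h_u    = sum_P w_P h_u^P          (final embedding)
// Targets with no instances fall back to their transformed feature
// vector.  With attention == false both softmax stages are replaced by
// uniform weights (the ablated mean-encoder variant).
//
// Gradients are analytic; the loss couples targets only through the
// final embeddings, so backpropagation runs independently per target
// and accumulates into dL/dH (transformed node vectors, folded into the
// linear maps on the R side) and the attention parameter matrices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

struct TypeCache {
  int t;        // 0-based type id
  int r0, r1;   // 0-based inclusive instance-row range
  vec pre;      // raw pre-ReLU instance attention scores
  vec w;        // instance weights (softmax of ReLU(pre), or uniform)
  vec hP;       // sigmoid-encoded type vector
};

struct NodeCache {
  bool fallback;
  rowvec emb;
  std::vector<TypeCache> tc;
  vec s_raw;    // raw pre-ReLU type scores
  vec wt;       // type weights
};

static inline void instance_mean(const IntegerMatrix &paths,
                                 const IntegerVector &plen, int row,
                                 const mat &H, rowvec &out) {
  const int L = plen[row];
  out.zeros();
  for (int p = 0; p <= L; ++p) out += H.row(paths(row, p) - 1);
  out /= (L + 1);
}

static void forward_one(int u, const mat &H, const IntegerMatrix &paths,
                        const IntegerVector &plen,
                        const IntegerVector &grp_start,
                        const IntegerVector &grp_end,
                        const IntegerVector &grp_type,
                        const IntegerVector &node_g0,
                        const IntegerVector &node_g1, const mat &att_i,
                        const mat &att_t, bool attention, NodeCache &nc) {
  const int z = H.n_cols;
  nc.tc.clear();
  const int g0 = node_g0[u], g1 = node_g1[u];
  if (g0 == 0) {
    nc.fallback = true;
    nc.emb = H.row(u);
    return;
  }
  nc.fallback = false;
  const rowvec hu = H.row(u);
  const int K = g1 - g0 + 1;
  mat hP(K, z);
  rowvec e(z);
  for (int gi = 0; gi < K; ++gi) {
    const int g = g0 - 1 + gi;
    TypeCache c;
    c.t = grp_type[g] - 1;
    c.r0 = grp_start[g] - 1;
    c.r1 = grp_end[g] - 1;
    const int k = c.r1 - c.r0 + 1;
    c.pre.set_size(k);
    vec m(z, arma::fill::zeros);
    if (attention) {
      const vec a1 = att_i.col(c.t).head(z);
      const vec a2 = att_i.col(c.t).tail(z);
      const double hu_a1 = arma::dot(hu.t(), a1);
      mat E(k, z);
      for (int i = 0; i < k; ++i) {
        instance_mean(paths, plen, c.r0 + i, H, e);
        E.row(i) = e;
        c.pre[i] = hu_a1 + arma::dot(e.t(), a2);
      }
      vec act = arma::clamp(c.pre, 0.0, arma::datum::inf);
      act -= act.max();                       // softmax max-subtraction
      c.w = arma::exp(act);
      c.w /= arma::accu(c.w);
      m = E.t() * c.w;
    } else {
      c.pre.zeros();
      c.w.set_size(k);
      c.w.fill(1.0 / k);
      for (int i = 0; i < k; ++i) {
        instance_mean(paths, plen, c.r0 + i, H, e);
        m += e.t();
      }
      m /= k;
    }
    c.hP = 1.0 / (1.0 + arma::exp(-m));
    hP.row(gi) = c.hP.t();
    nc.tc.push_back(std::move(c));
  }
  nc.s_raw.set_size(K);
  nc.wt.set_size(K);
  if (attention) {
    for (int gi = 0; gi < K; ++gi)
      nc.s_raw[gi] = arma::dot(att_t.col(nc.tc[gi].t), nc.tc[gi].hP);
    vec act = arma::clamp(nc.s_raw, 0.0, arma::datum::inf);
    act -= act.max();
    nc.wt = arma::exp(act);
    nc.wt /= arma::accu(nc.wt);
  } else {
    nc.s_raw.zeros();
    nc.wt.fill(1.0 / K);
  }
  nc.emb = nc.wt.t() * hP;
}

static void backward_one(int u, const rowvec &g, const mat &H,
                         const IntegerMatrix &paths,
                         const IntegerVector &plen, const mat &att_i,
                         const mat &att_t, bool attention,
                         const NodeCache &nc, mat &G_H, mat &G_att_i,
                         mat &G_att_t) {
  if (nc.fallback) {
    G_H.row(u) += g;
    return;
  }
  const int z = H.n_cols;
  const int K = nc.tc.size();
  const rowvec hu = H.row(u);
  // type-fusion stage
  vec q(K);
  for (int gi = 0; gi < K; ++gi) q[gi] = arma::dot(g.t(), nc.tc[gi].hP);
  vec ds(K, arma::fill::zeros);
  if (attention) {
    const double wq = arma::dot(nc.wt, q);
    ds = nc.wt % (q - wq);                   // dL/ds through the softmax
  }
  rowvec g_hu(z, arma::fill::zeros);
  rowvec e(z);
  for (int gi = 0; gi < K; ++gi) {
    const TypeCache &c = nc.tc[gi];
    vec g_hP = nc.wt[gi] * g.t();
    if (attention && nc.s_raw[gi] > 0) {     // ReLU gate on the type score
      G_att_t.col(c.t) += ds[gi] * c.hP;
      g_hP += ds[gi] * att_t.col(c.t);
    }
    const vec dm = g_hP % c.hP % (1.0 - c.hP);   // through sigmoid
    const int k = c.r1 - c.r0 + 1;
    vec dw(k);
    mat E(k, z);
    for (int i = 0; i < k; ++i) {
      instance_mean(paths, plen, c.r0 + i, H, e);
      E.row(i) = e;
      dw[i] = arma::dot(dm, e.t());
    }
    vec de(k, arma::fill::zeros);
    vec a1, a2;
    if (attention) {
      a1 = att_i.col(c.t).head(z);
      a2 = att_i.col(c.t).tail(z);
      const double wdw = arma::dot(c.w, dw);
      de = c.w % (dw - wdw);
    }
    double de_relu_sum = 0.0;
    for (int i = 0; i < k; ++i) {
      vec gE = c.w[i] * dm;
      if (attention && c.pre[i] > 0) {       // ReLU gate on instance score
        gE += de[i] * a2;
        G_att_i.col(c.t).tail(z) += de[i] * E.row(i).t();
        de_relu_sum += de[i];
      }
      const int row = c.r0 + i;
      const int L = plen[row];
      const rowvec gEr = gE.t() / (L + 1);
      for (int p = 0; p <= L; ++p) G_H.row(paths(row, p) - 1) += gEr;
    }
    if (attention && de_relu_sum != 0.0) {
      G_att_i.col(c.t).head(z) += de_relu_sum * hu.t();
      g_hu += de_relu_sum * a1.t();
    }
  }
  G_H.row(u) += g_hu;
}

// Final embeddings of the requested targets (1-based node indices).
// [[Rcpp::export]]
arma::mat cpp_embed(const arma::mat &H, IntegerMatrix paths,
                    IntegerVector plen, IntegerVector grp_start,
                    IntegerVector grp_end, IntegerVector grp_type,
                    IntegerVector node_g0, IntegerVector node_g1,
                    const arma::mat &att_inst, const arma::mat &att_type,
                    IntegerVector targets, bool attention) {
  mat out(targets.size(), H.n_cols);
  NodeCache nc;
  for (int i = 0; i < targets.size(); ++i) {
    forward_one(targets[i] - 1, H, paths, plen, grp_start, grp_end,
                grp_type, node_g0, node_g1, att_inst, att_type, attention,
                nc);
    out.row(i) = nc.emb;
  }
  return out;
}

// Contrastive loss over node pairs and (optionally) its gradients with
// respect to the transformed node vectors H and the attention
// parameters.  psign is +1 for positive pairs (the log-sigmoid term is
// added) and -1 for negatives (subtracted); minimising pulls positive
// pairs together in Manhattan distance and pushes negatives apart.
// [[Rcpp::export]]
List cpp_loss_grad(const arma::mat &H, IntegerMatrix paths,
                   IntegerVector plen, IntegerVector grp_start,
                   IntegerVector grp_end, IntegerVector grp_type,
                   IntegerVector node_g0, IntegerVector node_g1,
                   const arma::mat &att_inst, const arma::mat &att_type,
                   IntegerVector pu, IntegerVector pv, NumericVector psign,
                   bool attention, bool want_grad) {
  const int N = H.n_rows, z = H.n_cols;
  std::vector<int> idx(N, -1);
  std::vector<int> uniq;
  for (int i = 0; i < pu.size(); ++i) {
    for (int node : {pu[i] - 1, pv[i] - 1}) {
      if (node < 0 || node >= N) stop("pair node index out of range");
      if (idx[node] < 0) {
        idx[node] = uniq.size();
        uniq.push_back(node);
      }
    }
  }
  std::vector<NodeCache> caches(uniq.size());
  for (size_t i = 0; i < uniq.size(); ++i)
    forward_one(uniq[i], H, paths, plen, grp_start, grp_end, grp_type,
                node_g0, node_g1, att_inst, att_type, attention, caches[i]);

  double loss = 0.0;
  mat G_emb;
  if (want_grad) G_emb.zeros(uniq.size(), z);
  for (int i = 0; i < pu.size(); ++i) {
    const int iu = idx[pu[i] - 1], iv = idx[pv[i] - 1];
    const rowvec diff = caches[iu].emb - caches[iv].emb;
    const double d = arma::accu(arma::abs(diff));
    loss += psign[i] * (-std::log1p(std::exp(-d)));  // log sigmoid(d), d >= 0
    if (want_grad) {
      const double c = psign[i] * (1.0 - 1.0 / (1.0 + std::exp(-d)));
      const rowvec gvec = c * arma::sign(diff);
      G_emb.row(iu) += gvec;
      G_emb.row(iv) -= gvec;
    }
  }
  if (!want_grad) {
    if (!std::isfinite(loss)) stop("non-finite loss");
    return List::create(_["loss"] = loss);
  }
  mat G_H(N, z, arma::fill::zeros);
  mat G_att_i(att_inst.n_rows, att_inst.n_cols, arma::fill::zeros);
  mat G_att_t(att_type.n_rows, att_type.n_cols, arma::fill::zeros);
  for (size_t i = 0; i < uniq.size(); ++i) {
    const rowvec g = G_emb.row(i);
    backward_one(uniq[i], g, H, paths, plen, att_inst, att_type, attention,
                 caches[i], G_H, G_att_i, G_att_t);
  }
  if (!std::isfinite(loss)) stop("non-finite loss");
  return List::create(_["loss"] = loss, _["G_H"] = G_H,
                      _["G_att_inst"] = G_att_i, _["G_att_type"] = G_att_t);
}
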