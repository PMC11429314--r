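# Desk-scale trained controller, shared by the acceptance checks that need
# it (training once keeps the suite inside its time budget). The
# configuration is the package's desk-scale setting: patient 10 (77 kg),
# piecewise reward, 1-day episodes matching the 1-day test horizon,
# width-64 replica of the block architecture, 2e5 environment steps.
.agent_cache <- new.env(parent = emptyenv())

desk_scale_agent <- function() {
  if (is.null(.agent_cache$agent)) {
    env <- glyco_env(ivp_patient(10), reward = "piecewise", episode_days = 1)
    .agent_cache$agent <- ppo_train(env, ppo_config(total_steps = 2e5),
                                    arch = ppo_arch(width = 64), seed = 2024)
  }
  .agent_cache$agent
}
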